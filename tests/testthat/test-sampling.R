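test_that("false-colour channels are band means with a percentile stretch", {
  g <- tiny_grid()
  flat <- flat_cube(rep(0.5, grid_length(g)), nr = 6, nc = 6, grid = g)
  fc <- build_false_colour(flat)
  expect_equal(fc[, , 1], fc[, , 2])
  expect_equal(fc[, , 2], fc[, , 3])
  expect_error(build_false_colour(flat, band_ranges = list(red = c(700, 720),
                                                           green = c(500, 580),
                                                           blue = c(450, 500))),
               "parameter error")
  # haemoglobin-loaded (vessel-like) pixels are darker in the green channel
  sc <- simulate_cube(grid = g, size = c(64, 64), noise_sd = 0, seed = 5,
                      vessel_strength = 0.8, fovea_sigma = 6, onh_radius = 5)
  fc2 <- build_false_colour(sc$cube)
  green <- fc2[, , 2]
  on_vessel <- sc$truth$vessel_centreline
  off_vessel <- !sc$truth$vessel_mask
  expect_lt(mean(green[on_vessel]), mean(green[off_vessel]))
})

test_that("raphe angle follows the fovea-to-ONH vector and is equivariant", {
  expect_equal(compute_raphe_angle(landmarks(c(100, 100), c(100, 200))), 0)
  expect_equal(compute_raphe_angle(landmarks(c(100, 100), c(200, 100))), pi / 2)
  expect_error(landmarks(c(10, 10), c(10, 10)), "coincide")
  # rotation by th in the (col = x, row = y) frame advances the angle by th
  rot <- function(rc, th) c(rc[1] * cos(th) + rc[2] * sin(th),
                            rc[2] * cos(th) - rc[1] * sin(th))
  set.seed(3)
  for (i in 1:5) {
    f <- runif(2, 50, 150); o <- runif(2, 200, 300); th <- runif(1, -1, 1)
    a0 <- compute_raphe_angle(landmarks(f, o))
    a1 <- compute_raphe_angle(landmarks(rot(f, th), rot(o, th)))
    delta <- (a1 - a0 - th) %% (2 * pi)
    expect_lt(min(delta, 2 * pi - delta), 1e-10)
  }
})

test_that("ROI masks match brute-force geometry and template invariants", {
  tp <- roi_template(f1_diameter = 16, f2_inner_diameter = 24,
                     f2_outer_diameter = 40, square_side = 30,
                     offset_fovea = 60, offset_onh = 60)
  lm <- landmarks(c(130, 80), c(130, 160))
  rois <- build_roi_masks(lm, c(260, 260), tp)
  # F1 pixel count equals the lattice-point count of the disc
  count <- 0
  for (r in 1:260) for (cl in 1:260) {
    if ((r - 130)^2 + (cl - 80)^2 <= 8^2) count <- count + 1
  }
  expect_equal(sum(rois$masks$F1), count)
  expect_equal(sum(rois$masks$F1 & rois$masks$F2), 0)
  # horizontal raphe: squares are axis-aligned with exact pixel counts
  expect_equal(rois$raphe_angle, 0)
  expect_equal(sum(rois$masks$S1), 31^2)  # |a|<=15 spans 31 integer offsets
  # S1 superior (smaller rows) than I1
  expect_lt(mean(row(rois$masks$S1)[rois$masks$S1]),
            mean(row(rois$masks$I1)[rois$masks$I1]))
  # rotation equivariance at the full template scale: pixel counts stable
  # to 1% (rasterisation only)
  lm_f <- landmarks(c(550, 360), c(550, 660))
  rois_f <- build_roi_masks(lm_f, c(1100, 1100))
  lm_f_rot <- landmarks(c(550, 360),
                        c(550 + 300 * sin(0.4), 360 + 300 * cos(0.4)))
  rois_f_rot <- build_roi_masks(lm_f_rot, c(1100, 1100))
  for (nm in names(rois_f$masks)) {
    expect_lt(abs(sum(rois_f_rot$masks[[nm]]) - sum(rois_f$masks[[nm]])) /
                sum(rois_f$masks[[nm]]), 0.01)
  }
  # out-of-bounds regions are reported by name
  expect_error(build_roi_masks(landmarks(c(20, 80), c(20, 160)), c(260, 260), tp),
               "S1|F2")
})

test_that("human vessel segmentation flags exactly the top 40% with dark-line sensitivity", {
  set.seed(17)
  img <- matrix(runif(200 * 200), 200, 200)
  vm <- segment_vessels_human(img)
  expect_equal(sum(vm$mask), ceiling(0.40 * 200 * 200))
  expect_equal(vm$n_flagged, 16000)
  # constant image: fraction still exact, tie-break fills lowest (row, col)
  vm_const <- segment_vessels_human(matrix(1, 50, 50))
  expect_equal(sum(vm_const$mask), ceiling(0.40 * 2500))
  idx <- which(vm_const$mask)
  rows <- (idx - 1) %% 50 + 1; cols <- (idx - 1) %/% 50 + 1
  ord_lex <- order(rows, cols)
  first_k <- cbind(rep(1:50, each = 50), rep(1:50, times = 50))[1:1000, ]
  expect_true(all(vm_const$mask[first_k]))
  # a dark 5-px line on a bright background is almost fully captured
  line_img <- matrix(1, 120, 120)
  line_img[, 58:62] <- 0.2
  vml <- segment_vessels_human(line_img, vessel_fraction = 0.40)
  expect_gte(mean(vml$mask[, 58:62]), 0.95)
  expect_error(segment_vessels_human(array(0, c(3, 3, 3))), "type error")
})

test_that("mouse segmentation generalises the human operator across scales", {
  set.seed(19)
  img <- matrix(runif(80 * 80), 80, 80)
  a <- segment_vessels_mouse(img, small_sigmas = 1, large_sigmas = 20)
  b <- segment_vessels_human(img)
  expect_identical(a$mask, b$mask)
  # vessels of width 2-12 px are all captured
  phantom <- matrix(1, 150, 150)
  cols_used <- list()
  at <- 15
  for (w in c(2, 4, 8, 12)) {
    phantom[, at:(at + w - 1)] <- 0.2
    cols_used[[as.character(w)]] <- at:(at + w - 1)
    at <- at + w + 22
  }
  vm <- segment_vessels_mouse(phantom)
  for (w in names(cols_used)) {
    expect_gte(mean(vm$mask[, cols_used[[w]]]), 0.95)
  }
  expect_equal(sum(vm$mask), ceiling(0.40 * 150 * 150))
  # ONH disc joins the exclusion mask
  vm_onh <- segment_vessels_mouse(phantom, onh_rc = c(75, 110), onh_radius = 8)
  expect_true(all(vm_onh$mask[sqrt((row(phantom) - 75)^2 +
                                     (col(phantom) - 110)^2) <= 8]))
})

test_that("ROI spectrum extraction averages log pixels then smooths", {
  g <- human_grid(); p <- grid_length(g)
  profile <- log(seq(0.3, 0.8, length.out = p))
  cube <- hs_cube(array(rep(profile, each = 64), c(8, 8, p)), g, space = "log")
  roi <- matrix(TRUE, 8, 8)
  sp <- extract_roi_spectrum(cube, roi, location_id = "S1")
  # constant-in-space cube: smoothing of the profile itself
  expect_equal(sp$values, savgol_smooth(profile), tolerance = 1e-10)
  expect_identical(sp$location_id, "S1")
  # perfect vessel exclusion recovers the background exactly
  d <- array(rep(profile, each = 64), c(8, 8, p))
  vessel <- matrix(FALSE, 8, 8); vessel[3:4, ] <- TRUE
  d[3:4, , ] <- d[3:4, , ] - 0.5
  cube2 <- hs_cube(d, g, space = "log")
  sp2 <- extract_roi_spectrum(cube2, roi, vessel_mask = vessel, smooth = FALSE)
  expect_equal(sp2$values, profile, tolerance = 1e-12)
  # pixel-permutation invariance within the ROI
  set.seed(7)
  d3 <- array(rnorm(64 * p), c(8, 8, p))
  cube3 <- hs_cube(d3, g, space = "log")
  perm <- sample(64)
  d3p <- array(matrix(d3, 64, p)[perm, ], c(8, 8, p))
  cube3p <- hs_cube(d3p, g, space = "log")
  expect_equal(extract_roi_spectrum(cube3, roi, smooth = FALSE)$values,
               extract_roi_spectrum(cube3p, roi, smooth = FALSE)$values,
               tolerance = 1e-12)
  # exclusion errors
  expect_error(extract_roi_spectrum(cube3, roi, vessel_mask = matrix(TRUE, 8, 8)),
               "sampling error")
  refl <- hs_cube(exp(d3), g)
  expect_error(extract_roi_spectrum(refl, roi), "log-space")
})

test_that("noiseless synthetic cube ROI mean matches the closed-form model", {
  g <- tiny_grid()
  sc <- simulate_cube(grid = g, size = c(64, 64), noise_sd = 0, seed = 9,
                      n_vessels = 0, fovea_sigma = 5, onh_radius = 4,
                      onh_brightness = 0, mp_strength = 0)
  lc <- log_transform(sc$cube)
  roi <- matrix(FALSE, 64, 64); roi[40:60, 5:25] <- TRUE
  sp <- extract_roi_spectrum(lc, roi, smooth = FALSE)
  expect_equal(sp$values, unname(sc$truth$base_log_spectrum), tolerance = 1e-9)
})
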