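#' Retinal landmarks
#'
#' Manually selected centres of the fovea and the optic nerve head (ONH), in
#' image coordinates `(row, col)`, 1-based with the origin at the top-left.
#'
#' @param fovea_rc,onh_rc Numeric `(row, col)` pairs; must differ.
#' @return A `landmarks` object.
#' @export
landmarks <- function(fovea_rc, onh_rc) {
  stopifnot(length(fovea_rc) == 2, length(onh_rc) == 2,
            all(is.finite(c(fovea_rc, onh_rc))))
  if (all(fovea_rc == onh_rc)) {
    stop("geometry error: fovea and ONH coincide")
  }
  l <- list(fovea_rc = as.numeric(fovea_rc), onh_rc = as.numeric(onh_rc))
  class(l) <- "landmarks"
  l
}

#' False-colour composite of a cube
#'
#' Merges spectral bands into an RGB image that enhances the visibility of
#' the vasculature, fovea and ONH: each channel is the mean reflectance over
#' its wavelength band, percentile-stretched to \[0, 1\].
#'
#' @param cube An [hs_cube()] in reflectance space.
#' @param band_ranges Named list of `c(low, high)` nm ranges for channels
#'   `red`, `green`, `blue` (defaults 600-700, 500-580, 450-500 nm).
#' @param stretch_quantiles Percentile pair for the contrast stretch.
#' @return Numeric array rows x cols x 3 (R, G, B) in \[0, 1\].
#' @export
build_false_colour <- function(cube,
                               band_ranges = list(red = c(600, 700),
                                                  green = c(500, 580),
                                                  blue = c(450, 500)),
                               stretch_quantiles = c(0.01, 0.99)) {
  stopifnot(inherits(cube, "hs_cube"))
  stopifnot(all(c("red", "green", "blue") %in% names(band_ranges)))
  lam <- cube$grid$values
  d <- dim(cube$data)
  out <- array(0, c(d[1], d[2], 3))
  for (i in 1:3) {
    rng <- band_ranges[[c("red", "green", "blue")[i]]]
    sel <- which(lam >= rng[1] & lam <= rng[2])
    if (length(sel) == 0) {
      stop("parameter error: band ", paste(rng, collapse = "-"),
           " nm contains no grid wavelength")
    }
    ch <- apply(cube$data[, , sel, drop = FALSE], c(1, 2), mean)
    q <- stats::quantile(ch, stretch_quantiles, names = FALSE)
    ch <- if (q[2] > q[1]) (ch - q[1]) / (q[2] - q[1]) else ch * 0
    out[, , i] <- pmin(pmax(ch, 0), 1)
  }
  out
}

#' Temporal raphe orientation
#'
#' Angle of the fovea-to-ONH line relative to the image row axis
#' (column direction), in radians in `(-pi, pi]`; row-down is positive,
#' so a purely vertical fovea-to-ONH displacement gives `pi/2`.
#'
#' @param landmarks A [landmarks()] object.
#' @return Angle in radians.
#' @export
compute_raphe_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmarks"))
  d <- landmarks$onh_rc - landmarks$fovea_rc
  atan2(d[1], d[2])
}

#' ROI template parameters
#'
#' Geometry of the six sampling regions, in pixels: the foveolar disc `F1`
#' (60 px diameter), the parafoveal annulus `F2` (inner/outer diameters
#' 100/200 px), and four 200 x 200 px squares displaced perpendicular to
#' the temporal raphe — `S1`/`I1` superior/inferior to the fovea, `S2`/`I2`
#' superior/inferior to the ONH (default offsets 300 px).
#'
#' @param f1_diameter,f2_inner_diameter,f2_outer_diameter,square_side
#'   Region sizes in pixels.
#' @param offset_fovea,offset_onh Perpendicular displacements of the square
#'   centres from the fovea and ONH, in pixels.
#' @return A named list of template parameters.
#' @export
roi_template <- function(f1_diameter = 60, f2_inner_diameter = 100,
                         f2_outer_diameter = 200, square_side = 200,
                         offset_fovea = 300, offset_onh = 300) {
  stopifnot(f2_inner_diameter > f1_diameter,
            f2_outer_diameter > f2_inner_diameter)
  list(f1_diameter = f1_diameter, f2_inner_diameter = f2_inner_diameter,
       f2_outer_diameter = f2_outer_diameter, square_side = square_side,
       offset_fovea = offset_fovea, offset_onh = offset_onh)
}

square_mask <- function(rr, cc, centre, side, u, nvec) {
  dr <- rr - centre[1]; dc <- cc - centre[2]
  a <- dr * u[1] + dc * u[2]
  b <- dr * nvec[1] + dc * nvec[2]
  abs(a) <= side / 2 & abs(b) <= side / 2
}

square_corners <- function(centre, side, u, nvec) {
  h <- side / 2
  rbind(centre + h * u + h * nvec, centre + h * u - h * nvec,
        centre - h * u + h * nvec, centre - h * u - h * nvec)
}

#' Build the six raphe-aligned sampling masks
#'
#' Constructs boolean masks for the regions of [roi_template()], oriented by
#' the temporal raphe (fovea-ONH line). Disc and annulus membership uses
#' Euclidean distance from the fovea centre (`<= radius`); squares have
#' sides aligned with the raphe axis. "Superior" is towards smaller row
#' indices when the raphe is horizontal, and rotates rigidly with it.
#'
#' @param landmarks A [landmarks()] object.
#' @param image_shape `c(rows, cols)`.
#' @param template A [roi_template()].
#' @return An `roi_set`: list with `masks` (named list of logical matrices
#'   `F1`, `F2`, `S1`, `S2`, `I1`, `I2`) and `raphe_angle`.
#' @export
build_roi_masks <- function(landmarks, image_shape, template = roi_template()) {
  stopifnot(inherits(landmarks, "landmarks"), length(image_shape) == 2)
  nr <- image_shape[1]; nc <- image_shape[2]
  theta <- compute_raphe_angle(landmarks)
  u <- c(sin(theta), cos(theta))      # along the raphe (fovea -> ONH)
  nvec <- c(-u[2], u[1])              # perpendicular; points superior at theta = 0
  fov <- landmarks$fovea_rc; onh <- landmarks$onh_rc
  tp <- template

  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  dist_fov <- sqrt((rr - fov[1])^2 + (cc - fov[2])^2)

  centres <- list(
    S1 = fov + tp$offset_fovea * nvec,
    I1 = fov - tp$offset_fovea * nvec,
    S2 = onh + tp$offset_onh * nvec,
    I2 = onh - tp$offset_onh * nvec
  )

  in_bounds <- function(pts) {
    all(pts[, 1] >= 1 & pts[, 1] <= nr & pts[, 2] >= 1 & pts[, 2] <= nc)
  }
  disc_in_bounds <- function(centre, radius) {
    centre[1] - radius >= 1 && centre[1] + radius <= nr &&
      centre[2] - radius >= 1 && centre[2] + radius <= nc
  }
  bad <- character(0)
  if (!disc_in_bounds(fov, tp$f1_diameter / 2)) bad <- c(bad, "F1")
  if (!disc_in_bounds(fov, tp$f2_outer_diameter / 2)) bad <- c(bad, "F2")
  for (nm in names(centres)) {
    if (!in_bounds(square_corners(centres[[nm]], tp$square_side, u, nvec))) {
      bad <- c(bad, nm)
    }
  }
  if (length(bad) > 0) {
    stop("geometry error: region(s) outside image bounds: ",
         paste(bad, collapse = ", "))
  }

  masks <- list(
    F1 = dist_fov <= tp$f1_diameter / 2,
    F2 = dist_fov >= tp$f2_inner_diameter / 2 &
         dist_fov <= tp$f2_outer_diameter / 2,
    S1 = square_mask(rr, cc, centres$S1, tp$square_side, u, nvec),
    S2 = square_mask(rr, cc, centres$S2, tp$square_side, u, nvec),
    I1 = square_mask(rr, cc, centres$I1, tp$square_side, u, nvec),
    I2 = square_mask(rr, cc, centres$I2, tp$square_side, u, nvec)
  )
  res <- list(masks = masks, raphe_angle = theta, centres = centres,
              template = tp)
  class(res) <- "roi_set"
  res
}

# Separable Gaussian blur with replicate boundary, by direct convolution.
# Direct (non-FFT) evaluation keeps the arithmetic position-independent, so
# a constant image blurs to an exactly constant image and the downstream
# quantile tie-break contract holds on degenerate inputs. The kernel radius
# is 3 sigma, capped at the image size.
gauss_blur <- function(image, sigma) {
  h <- ceiling(3 * sigma)
  conv_rows <- function(M) {
    nr <- nrow(M)
    hh <- min(h, nr - 1)
    k <- stats::dnorm(-hh:hh, sd = sigma)
    k <- k / sum(k)
    pad <- M[c(rep(1, hh), seq_len(nr), rep(nr, hh)), , drop = FALSE]
    out <- stats::filter(pad, k, sides = 2)
    matrix(out[(hh + 1):(hh + nr), ], nr, ncol(M))
  }
  t(conv_rows(t(conv_rows(image))))
}

# Quantile-threshold a vessel-response image: flag the top `fraction` of
# pixels inside `region`, ties broken towards lowest (row, col) so the
# flagged count is exactly ceiling(fraction * N).
threshold_response <- function(response, fraction, region = NULL) {
  nr <- nrow(response); nc <- ncol(response)
  if (is.null(region)) region <- matrix(TRUE, nr, nc)
  stopifnot(all(dim(region) == dim(response)))
  idx <- which(region)
  n <- length(idx)
  if (n == 0) stop("sampling error: empty evaluation region")
  k <- ceiling(fraction * n)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ord <- order(-response[idx], rows, cols)
  mask <- matrix(FALSE, nr, nc)
  mask[idx[ord[seq_len(k)]]] <- TRUE
  res <- list(mask = mask, fraction = k / n, n_flagged = k)
  class(res) <- "vessel_mask"
  res
}

#' Segment retinal vessels (human variant)
#'
#' Difference-of-Gaussians vessel enhancement on the green channel of the
#' false-colour image: `DoG = G(sigma_large)*I - G(sigma_small)*I`, so dark
#' curvilinear structures score high, followed by quantile thresholding —
#' the top `vessel_fraction` (default 40%) of pixels by DoG value are
#' flagged as vessel. Ties are broken towards the lowest `(row, col)` so
#' exactly `ceiling(fraction * N)` pixels are flagged for any input.
#'
#' @param image 2-D numeric matrix (typically the green channel).
#' @param sigma_small,sigma_large Gaussian standard deviations in pixels
#'   (defaults 1 and 20).
#' @param vessel_fraction Fraction of pixels to flag (default 0.40).
#' @param region Optional logical matrix restricting evaluation (e.g. one
#'   sampling region); the quantile is taken within it.
#' @return A `vessel_mask`: list with logical `mask`, achieved `fraction`
#'   and `n_flagged`.
#' @export
segment_vessels_human <- function(image, sigma_small = 1, sigma_large = 20,
                                  vessel_fraction = 0.40, region = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("type error: image must be a 2-D numeric matrix")
  }
  if (!all(is.finite(image))) stop("type error: image must be finite")
  stopifnot(sigma_small < sigma_large, vessel_fraction > 0, vessel_fraction <= 1)
  dog <- gauss_blur(image, sigma_large) - gauss_blur(image, sigma_small)
  threshold_response(dog, vessel_fraction, region)
}

#' Segment retinal vessels (mouse variant)
#'
#' Multi-scale difference-of-Gaussians segmentation for the mouse imaging
#' system, applied to the mean image over 390-460 nm: the response is the
#' pointwise maximum of the signed DoG over all `(sigma_small, sigma_large)`
#' pairs with `sigma_small < sigma_large` (defaults: small 1-5 in 0.2
#' steps, large 4-14 in 1 steps), capturing vessels of a range of calibres.
#' Thresholding is as in [segment_vessels_human()]; when landmarks are
#' supplied the optic-nerve-head disc is also flagged for exclusion.
#'
#' @inheritParams segment_vessels_human
#' @param small_sigmas,large_sigmas Numeric vectors of Gaussian SDs (px).
#' @param onh_rc Optional ONH centre `(row, col)`; its disc is added to the
#'   exclusion mask.
#' @param onh_radius ONH disc radius in pixels (default 40).
#' @return A `vessel_mask` (the `fraction` field reports the DoG-flagged
#'   fraction before ONH addition).
#' @export
segment_vessels_mouse <- function(image, small_sigmas = seq(1, 5, by = 0.2),
                                  large_sigmas = seq(4, 14, by = 1),
                                  vessel_fraction = 0.40, region = NULL,
                                  onh_rc = NULL, onh_radius = 40) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("type error: image must be a 2-D numeric matrix")
  }
  if (!all(is.finite(image))) stop("type error: image must be finite")
  small_cache <- lapply(small_sigmas, function(s) gauss_blur(image, s))
  large_cache <- lapply(large_sigmas, function(s) gauss_blur(image, s))
  response <- NULL
  for (i in seq_along(small_sigmas)) {
    for (j in seq_along(large_sigmas)) {
      if (small_sigmas[i] >= large_sigmas[j]) next
      dog <- large_cache[[j]] - small_cache[[i]]
      response <- if (is.null(response)) dog else pmax(response, dog)
    }
  }
  if (is.null(response)) stop("parameter error: no sigma pair with small < large")
  res <- threshold_response(response, vessel_fraction, region)
  if (!is.null(onh_rc)) {
    rr <- row(image); cc <- col(image)
    res$mask <- res$mask | (sqrt((rr - onh_rc[1])^2 + (cc - onh_rc[2])^2) <= onh_radius)
  }
  res
}

#' Mean log-spectrum of a sampling region
#'
#' Averages the log-reflectance spectra of all pixels in
#' `roi & !vessel & valid`, then applies Savitzky-Golay smoothing
#' (order 5, width 13) along the wavelength axis — log before mean, and
#' smoothing on the region mean only.
#'
#' @param cube An [hs_cube()] in log space.
#' @param roi_mask Logical matrix selecting the region.
#' @param vessel_mask Optional `vessel_mask` (or logical matrix) of pixels
#'   to exclude.
#' @param location_id Location tag for the returned spectrum.
#' @param smooth Apply the Savitzky-Golay step (default `TRUE`).
#' @param sg_order,sg_window Smoothing parameters.
#' @return An [hs_spectrum()] in log space.
#' @export
extract_roi_spectrum <- function(cube, roi_mask, vessel_mask = NULL,
                                 location_id = NA_character_, smooth = TRUE,
                                 sg_order = 5, sg_window = 13) {
  stopifnot(inherits(cube, "hs_cube"))
  if (cube$space != "log") {
    stop("validation error: extract_roi_spectrum requires a log-space cube")
  }
  d <- dim(cube$data)
  stopifnot(is.matrix(roi_mask), all(dim(roi_mask) == d[1:2]))
  eff <- roi_mask
  if (!is.null(vessel_mask)) {
    vm <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else vessel_mask
    stopifnot(all(dim(vm) == d[1:2]))
    eff <- eff & !vm
  }
  if (!is.null(cube$valid)) eff <- eff & cube$valid
  if (!any(eff)) stop("sampling error: no pixels left in the region")
  M <- matrix(cube$data, d[1] * d[2], d[3])
  spec <- colMeans(M[as.vector(eff), , drop = FALSE])
  if (smooth) spec <- savgol_smooth(spec, order = sg_order, window = sg_window)
  hs_spectrum(spec, cube$grid, space = "log", subject_id = cube$subject_id,
              location_id = location_id, eye = cube$eye, session = cube$session)
}
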