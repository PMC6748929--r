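#' @importFrom stats rnorm
NULL

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

default_nuisance_sds <- function() {
  c(ocular_media = 0.10, macular_pigment = 0.06,
    melanin = 0.08, haemoglobin = 0.04)
}

# Fixed smooth log-reflectance baseline: fundus reflectance rises towards
# the near infrared.
baseline_log_spectrum <- function(grid) {
  -2.5 + 1.5 * stats::plogis((grid$values - 580) / 60)
}

#' Simulate a cohort of log-reflectance spectra
#'
#' Generates subject spectra with the mixture structure the discriminant
#' analysis assumes: for subject i,
#' `x_i = m + sum_j c_ij A_j + s_i * effect_size * noise_sd * beta + eps_i`,
#' where `m` is a fixed smooth baseline, `A_j` are the unit-norm nuisance
#' constituent shapes (ocular media, macular pigment, melanin, haemoglobin)
#' with loadings `c_ij ~ N(0, nuisance_sds[j])`, `beta` is the unit-norm
#' short-wavelength amyloid stand-in, `s_i` is 1 for cases and 0 for
#' controls, and `eps_i` is i.i.d. `N(0, noise_sd)` per wavelength. The
#' group separation is therefore `effect_size` residual-noise standard
#' deviations along `beta`.
#'
#' Generation is a pure function of the arguments: the same seed gives
#' bit-identical output and the caller's RNG state is left untouched.
#'
#' @param n_case,n_control Subject counts (defaults 15/20, the principal
#'   human cohort sizes).
#' @param effect_size Group shift along the amyloid axis in units of
#'   `noise_sd`. The default 1.3 corresponds to a theoretical AUC of
#'   `pnorm(1.3/sqrt(2))` (about 0.82) once nuisance axes are removed.
#' @param nuisance_sds Named numeric vector of per-constituent loading SDs
#'   (log-absorbance units); see [build_constituent_basis()] for names.
#' @param noise_sd Per-wavelength residual SD in log space.
#' @param grid A `wl_grid` (default: human 450-900 nm / 5 nm).
#' @param seed Integer seed.
#' @param foveal If `FALSE` (default), macular-pigment loading is forced to
#'   zero, emulating extrafoveal sampling locations.
#' @param location_id Location tag recorded in metadata.
#' @param truth Optional ground truth from a previous call: reuses its
#'   subject loadings and labels and redraws only the residual noise,
#'   emulating a repeat acquisition (e.g. the fellow eye) of the same
#'   subjects.
#' @return A list with `spectra` (a [spectrum_matrix()]) and `truth`
#'   (subject loadings, planted signature `beta`, labels, baseline, seed).
#' @export
simulate_cohort <- function(n_case = 15, n_control = 20, effect_size = 1.3,
                            nuisance_sds = default_nuisance_sds(),
                            noise_sd = 0.02,
                            grid = make_grid(450, 900, 5),
                            seed = 1, foveal = FALSE,
                            location_id = "S1", truth = NULL) {
  stopifnot(n_case >= 0, n_control >= 0, noise_sd >= 0, effect_size >= 0,
            all(nuisance_sds >= 0))
  basis <- build_constituent_basis(grid)
  nuis_names <- c("ocular_media", "macular_pigment", "melanin", "haemoglobin")
  sds <- default_nuisance_sds()
  sds[names(nuisance_sds)] <- nuisance_sds
  if (!foveal) sds["macular_pigment"] <- 0
  beta <- basis[, "abeta"]
  m <- baseline_log_spectrum(grid)
  p <- grid_length(grid)

  if (is.null(truth)) {
    n <- n_case + n_control
    labels <- rep(c("case", "control"), c(n_case, n_control))
    loadings <- with_local_seed(seed, {
      matrix(rnorm(n * length(nuis_names)), n, length(nuis_names),
             dimnames = list(NULL, nuis_names)) %*% diag(sds)
    })
    colnames(loadings) <- nuis_names
    noise_seed <- seed
  } else {
    loadings <- truth$loadings
    labels <- truth$labels
    n <- nrow(loadings)
    noise_seed <- seed + 1L
  }
  if (n < 1) stop("validation error: empty cohort")

  signal <- ifelse(labels == "case", 1, 0) * effect_size * noise_sd
  X <- matrix(m, n, p, byrow = TRUE) +
    loadings %*% t(basis[, nuis_names]) +
    outer(signal, beta)
  if (noise_sd > 0) {
    eps <- with_local_seed(noise_seed + 104729L,
                           matrix(rnorm(n * p, sd = noise_sd), n, p))
    X <- X + eps
  }
  meta <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                     eye = "study", location = location_id, session = "1",
                     stringsAsFactors = FALSE)
  out_truth <- list(loadings = loadings, beta = beta, labels = labels,
                    baseline = m, effect_size = effect_size,
                    noise_sd = noise_sd, nuisance_sds = sds, seed = seed)
  list(spectra = spectrum_matrix(X, labels, grid, metadata = meta),
       truth = out_truth)
}

#' Simulate a hyperspectral retinal cube
#'
#' Renders a single-subject cube from the generative model of
#' [simulate_cohort()] plus spatial structure: a fan of dark curvilinear
#' vessels with Gaussian cross-section (haemoglobin-weighted absorbance), a
#' foveal macular-pigment disc, and a bright optic-nerve-head (ONH) disc.
#' The true vessel mask and the landmark coordinates are returned as ground
#' truth.
#'
#' @param grid A `wl_grid`.
#' @param size Image size `c(rows, cols)` in pixels.
#' @param landmarks Optional [landmarks()]; defaults to a fovea at
#'   `(rows/2, 0.35*cols)` and an ONH at `(rows/2, 0.72*cols)`.
#' @param group `"control"` or `"case"` (adds the planted signature).
#' @param effect_size,nuisance_sds,noise_sd As in [simulate_cohort()].
#' @param n_vessels Number of vessel branches fanned out from the ONH.
#' @param vessel_width Gaussian cross-section scale in pixels; the truth
#'   mask covers pixels within `2 * vessel_width` of a centreline.
#' @param vessel_strength Peak haemoglobin absorbance added on vessel
#'   centrelines (log units).
#' @param fovea_sigma Gaussian radius of the macular-pigment disc (px).
#' @param mp_strength Peak macular-pigment absorbance at the foveola.
#' @param onh_radius,onh_brightness Radius (px) and flat log-reflectance
#'   boost of the bright ONH disc.
#' @param seed Integer seed.
#' @return A list with `cube` (an [hs_cube()]) and `truth` (vessel mask,
#'   centreline mask, landmarks, subject loadings, group).
#' @export
simulate_cube <- function(grid = make_grid(450, 900, 5), size = c(512, 512),
                          landmarks = NULL, group = c("control", "case"),
                          effect_size = 1.3,
                          nuisance_sds = default_nuisance_sds(),
                          noise_sd = 0.02, n_vessels = 6, vessel_width = 3,
                          vessel_strength = 0.5, fovea_sigma = 40,
                          mp_strength = 0.4, onh_radius = 40,
                          onh_brightness = 0.35, seed = 1) {
  group <- match.arg(group)
  nr <- size[1]; nc <- size[2]
  if (is.null(landmarks)) {
    landmarks <- landmarks(c(round(nr / 2), round(0.35 * nc)),
                           c(round(nr / 2), round(0.72 * nc)))
  }
  if (any(c(landmarks$fovea_rc, landmarks$onh_rc) < 1) ||
      any(landmarks$fovea_rc > c(nr, nc)) || any(landmarks$onh_rc > c(nr, nc))) {
    stop("geometry error: landmarks outside image bounds")
  }
  basis <- build_constituent_basis(grid)
  nuis_names <- c("ocular_media", "macular_pigment", "melanin", "haemoglobin")
  sds <- default_nuisance_sds()
  sds[names(nuisance_sds)] <- nuisance_sds
  p <- grid_length(grid)
  m <- baseline_log_spectrum(grid)

  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))

  draws <- with_local_seed(seed, {
    list(loadings = rnorm(length(nuis_names)) * sds,
         angles = stats::runif(n_vessels, -0.45 * pi, 0.45 * pi),
         curv = rnorm(n_vessels, 0, 25),
         noise = if (noise_sd > 0) rnorm(nr * nc * p, sd = noise_sd) else NULL)
  })
  loadings <- draws$loadings; names(loadings) <- nuis_names

  # Vessel centrelines: branches fanned from the ONH towards the temporal side.
  centre <- matrix(FALSE, nr, nc)
  onh <- landmarks$onh_rc
  L <- 0.9 * max(nr, nc)
  for (v in seq_len(n_vessels)) {
    a <- draws$angles[v]  # fan towards decreasing column (temporal)
    u <- c(sin(a), -cos(a))
    nvec <- c(-u[2], u[1])
    t_seq <- seq(0, 1, length.out = 4 * round(L))
    pts_r <- onh[1] + t_seq * L * u[1] + sin(t_seq * pi) * draws$curv[v] * nvec[1]
    pts_c <- onh[2] + t_seq * L * u[2] + sin(t_seq * pi) * draws$curv[v] * nvec[2]
    ir <- round(pts_r); ic <- round(pts_c)
    keep <- ir >= 1 & ir <= nr & ic >= 1 & ic <= nc
    centre[cbind(ir[keep], ic[keep])] <- TRUE
  }
  dist_vessel <- as.matrix(EBImage::distmap(1 - centre))
  vessel_profile <- exp(-dist_vessel^2 / (2 * vessel_width^2))
  vessel_mask <- dist_vessel <= 2 * vessel_width

  dist_fovea <- sqrt((rr - landmarks$fovea_rc[1])^2 + (cc - landmarks$fovea_rc[2])^2)
  fovea_profile <- exp(-dist_fovea^2 / (2 * fovea_sigma^2))
  dist_onh <- sqrt((rr - onh[1])^2 + (cc - onh[2])^2)
  onh_disc <- dist_onh <= onh_radius

  signal <- if (group == "case") effect_size * noise_sd else 0
  base_spec <- m + drop(basis[, nuis_names] %*% loadings) +
    signal * basis[, "abeta"]

  npix <- nr * nc
  logR <- matrix(base_spec, npix, p, byrow = TRUE)
  logR <- logR - (vessel_strength * as.vector(vessel_profile)) %o% basis[, "haemoglobin"]
  logR <- logR - (mp_strength * as.vector(fovea_profile)) %o% basis[, "macular_pigment"]
  logR <- logR + onh_brightness * as.vector(onh_disc)
  if (!is.null(draws$noise)) logR <- logR + matrix(draws$noise, npix, p)

  cube <- hs_cube(array(exp(logR), dim = c(nr, nc, p)), grid,
                  subject_id = "synthetic", eye = "study", session = "1")
  truth <- list(vessel_mask = vessel_mask, vessel_centreline = centre,
                landmarks = landmarks, loadings = loadings, group = group,
                base_log_spectrum = base_spec, seed = seed)
  list(cube = cube, truth = truth)
}
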