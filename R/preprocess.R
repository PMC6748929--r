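#' Calibrate raw counts to reflectance
#'
#' Applies the standard dark/white calibration: at each wavelength,
#' `reflectance = (frames - dark - internal_reflection) / (white - dark)`.
#' Negative values (shot noise around the dark level) are clipped to zero;
#' no upper clip is applied, so specular regions may exceed 1.
#'
#' @param raw A [raw_acquisition()].
#' @return An [hs_cube()] of reflectance.
#' @export
calibrate_reflectance <- function(raw) {
  stopifnot(inherits(raw, "raw_acquisition"))
  d <- dim(raw$frames)
  out <- array(0, dim = d)
  for (i in seq_len(d[3])) {
    denom <- raw$white[i] - raw$dark
    out[, , i] <- (raw$frames[, , i] - raw$dark - raw$internal_reflection[i]) / denom
  }
  out[out < 0] <- 0
  hs_cube(out, raw$grid)
}

# Integer-shift normalised cross-correlation between two frames.
# Returns the (drow, dcol) applied to `frame` that best aligns it to `ref`.
best_shift <- function(ref, frame, radius) {
  nr <- nrow(ref); nc <- ncol(ref)
  if (stats::sd(frame) == 0 || stats::sd(ref) == 0) {
    warning("registration: degenerate (constant) frame, using zero shift")
    return(c(0L, 0L))
  }
  best <- c(0L, 0L); best_ncc <- -Inf
  for (dr in -radius:radius) {
    r1 <- max(1, 1 + dr):min(nr, nr + dr)   # rows in ref
    r2 <- r1 - dr                            # rows in frame
    for (dc in -radius:radius) {
      c1 <- max(1, 1 + dc):min(nc, nc + dc)
      c2 <- c1 - dc
      a <- ref[r1, c1]; b <- frame[r2, c2]
      sa <- stats::sd(a); sb <- stats::sd(b)
      ncc <- if (sa == 0 || sb == 0) 0 else
        mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
      if (ncc > best_ncc + 1e-12 ||
          (abs(ncc - best_ncc) <= 1e-12 && sum(abs(c(dr, dc))) < sum(abs(best)))) {
        best_ncc <- ncc; best <- c(dr, dc)
      }
    }
  }
  best
}

shift_frame <- function(frame, dr, dc) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(NA_real_, nr, nc)
  r_dst <- max(1, 1 + dr):min(nr, nr + dr)
  c_dst <- max(1, 1 + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- frame[r_dst - dr, c_dst - dc]
  out
}

#' Register cube frames by integer translation
#'
#' Compensates residual inter-frame motion: each frame is aligned to its
#' neighbour by the integer shift maximising normalised cross-correlation,
#' and shifts are accumulated so every frame is expressed in the reference
#' frame's coordinates. Pixels shifted in from outside the field are marked
#' invalid in the cube's `valid` mask (and filled with zeros), so spatial
#' averages exclude them. Translation-only registration is deliberate: it is
#' sufficient for the small residual motion this step targets.
#'
#' @param cube An [hs_cube()] with at least 2 frames.
#' @param reference_index Frame whose coordinates define the output
#'   (default: middle frame).
#' @param search_radius Maximum shift searched, in pixels.
#' @return The registered [hs_cube()] with a `valid` mask and the applied
#'   per-frame shifts in attribute `shifts`.
#' @export
register_frames <- function(cube, reference_index = NULL, search_radius = 10) {
  stopifnot(inherits(cube, "hs_cube"))
  n <- dim(cube$data)[3]
  if (n < 2) stop("validation error: registration needs at least 2 frames")
  if (is.null(reference_index)) reference_index <- ceiling(n / 2)
  stopifnot(reference_index >= 1, reference_index <= n)

  # Pairwise neighbour shifts: rel[i] aligns frame i to frame i+1.
  rel <- matrix(0L, n, 2)
  for (i in seq_len(n - 1)) {
    rel[i, ] <- best_shift(cube$data[, , i + 1], cube$data[, , i], search_radius)
  }
  # Accumulate to the reference frame.
  shifts <- matrix(0L, n, 2)
  if (reference_index > 1) {
    for (i in (reference_index - 1):1) shifts[i, ] <- shifts[i + 1, ] + rel[i, ]
  }
  if (reference_index < n) {
    for (i in (reference_index + 1):n) shifts[i, ] <- shifts[i - 1, ] - rel[i - 1, ]
  }

  out <- cube$data
  valid <- matrix(TRUE, dim(out)[1], dim(out)[2])
  for (i in seq_len(n)) {
    if (any(shifts[i, ] != 0)) {
      sh <- shift_frame(cube$data[, , i], shifts[i, 1], shifts[i, 2])
      valid <- valid & !is.na(sh)
      sh[is.na(sh)] <- 0
      out[, , i] <- sh
    }
  }
  res <- hs_cube(out, cube$grid, pixel_scale_um = cube$pixel_scale_um,
                 subject_id = cube$subject_id, eye = cube$eye,
                 session = cube$session, valid = valid)
  attr(res, "shifts") <- shifts
  res
}

#' Log-transform reflectance
#'
#' Elementwise natural logarithm, turning the multiplicative interaction of
#' illumination, media transmission and tissue reflectance into additive
#' terms. Values below `floor` are raised to `floor` first, guarding
#' shot-noise zeros.
#'
#' @param x An [hs_cube()], [hs_spectrum()], or numeric vector/matrix/array
#'   of reflectances.
#' @param floor Reflectance floor applied before the log (default `1e-6`).
#' @return Same shape as the input, in log space (`space = "log"` for
#'   package objects).
#' @export
log_transform <- function(x, floor = 1e-6) {
  stopifnot(floor > 0)
  if (inherits(x, "hs_cube")) {
    if (x$space == "log") stop("domain error: cube already in log space")
    if (all(x$data == 0)) stop("domain error: all-zero cube cannot be log-transformed")
    return(hs_cube(log(pmax(x$data, floor)), x$grid,
                   pixel_scale_um = x$pixel_scale_um,
                   subject_id = x$subject_id, eye = x$eye,
                   session = x$session, valid = x$valid, space = "log"))
  }
  if (inherits(x, "hs_spectrum")) {
    if (x$space == "log") stop("domain error: spectrum already in log space")
    if (all(x$values == 0)) stop("domain error: all-zero spectrum")
    return(hs_spectrum(log(pmax(x$values, floor)), x$grid, space = "log",
                       subject_id = x$subject_id, location_id = x$location_id,
                       eye = x$eye, session = x$session))
  }
  if (all(x == 0)) stop("domain error: all-zero input")
  log(pmax(x, floor))
}

#' Savitzky-Golay spectral smoothing
#'
#' Local least-squares polynomial smoothing along the wavelength axis with
#' the study defaults: 5th-order kernel of width 13. Each value is replaced
#' by the centre of a polynomial fit over its window; the terminal
#' half-windows are handled by evaluating the polynomial fitted to the first
#' and last full windows at the edge positions.
#'
#' @param spectrum An [hs_spectrum()] or numeric vector.
#' @param order Polynomial order (default 5).
#' @param window Odd window width (default 13); the spectrum must be at
#'   least this long.
#' @return Smoothed object of the same type.
#' @export
savgol_smooth <- function(spectrum, order = 5, window = 13) {
  if (window %% 2 != 1) stop("parameter error: window must be odd")
  if (order >= window) stop("parameter error: order must be < window")
  v <- if (inherits(spectrum, "hs_spectrum")) spectrum$values else spectrum
  if (length(v) < window) {
    stop("parameter error: spectrum shorter than the smoothing window")
  }
  sm <- signal::sgolayfilt(v, p = order, n = window)
  if (inherits(spectrum, "hs_spectrum")) {
    out <- spectrum
    out$values <- sm
    out
  } else {
    sm
  }
}
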