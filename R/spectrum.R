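#' Construct a single spectrum
#'
#' A per-wavelength intensity vector tagged with its grid, intensity space
#' (linear reflectance or log-reflectance) and acquisition metadata. The
#' model-fitting and scoring operations require `space = "log"`.
#'
#' @param values Numeric vector, one value per grid wavelength; all finite.
#' @param grid A `wl_grid`.
#' @param space `"reflectance"` or `"log"`.
#' @param subject_id,location_id,eye,session Optional metadata. `location_id`
#'   is one of the six sampling regions (`F1`, `F2`, `S1`, `S2`, `I1`, `I2`)
#'   or `WHOLE` for whole-retina means.
#' @return An `hs_spectrum` object.
#' @export
hs_spectrum <- function(values, grid, space = c("reflectance", "log"),
                        subject_id = NA_character_, location_id = NA_character_,
                        eye = NA_character_, session = NA_character_) {
  space <- match.arg(space)
  stopifnot(inherits(grid, "wl_grid"), is.numeric(values))
  if (length(values) != grid_length(grid)) {
    stop("grid error: spectrum length ", length(values),
         " does not match grid length ", grid_length(grid))
  }
  if (!all(is.finite(values))) {
    stop("validation error: spectrum contains non-finite values")
  }
  s <- list(values = as.numeric(values), grid = grid, space = space,
            subject_id = subject_id, location_id = location_id,
            eye = eye, session = session)
  class(s) <- "hs_spectrum"
  s
}

#' @export
print.hs_spectrum <- function(x, ...) {
  cat(sprintf("<hs_spectrum> %s | %d wavelengths (%g-%g nm) | subject %s, location %s\n",
              x$space, length(x$values), x$grid$start_nm, x$grid$end_nm,
              x$subject_id, x$location_id))
  invisible(x)
}

#' Construct a cohort spectrum matrix
#'
#' The object the discriminant trains on: one row per subject spectrum
#' (log space), a two-level group label per row, and shared grid/location.
#'
#' @param X Numeric matrix, subjects x wavelengths, in log space.
#' @param labels Character or factor with levels `case` and `control`
#'   (at least one row of each is required for training).
#' @param grid A `wl_grid` with length `ncol(X)`.
#' @param metadata Optional data frame, one row per spectrum (subject, eye,
#'   location, session).
#' @return A `spectrum_matrix` object.
#' @export
spectrum_matrix <- function(X, labels, grid, metadata = NULL) {
  stopifnot(is.matrix(X), inherits(grid, "wl_grid"))
  if (ncol(X) != grid_length(grid)) {
    stop("grid error: matrix has ", ncol(X), " columns but grid has ",
         grid_length(grid), " wavelengths")
  }
  if (!all(is.finite(X))) {
    stop("validation error: spectrum matrix contains non-finite values")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) {
    stop("validation error: one label per row required")
  }
  if (!all(labels %in% c("case", "control"))) {
    stop("validation error: labels must be 'case' or 'control'")
  }
  if (!is.null(metadata)) {
    stopifnot(is.data.frame(metadata), nrow(metadata) == nrow(X))
  }
  m <- list(X = X, labels = labels, grid = grid, metadata = metadata)
  class(m) <- "spectrum_matrix"
  m
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d spectra x %d wavelengths (%d case / %d control)\n",
              nrow(x$X), ncol(x$X), sum(x$labels == "case"),
              sum(x$labels == "control")))
  invisible(x)
}
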