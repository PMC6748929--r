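#' Construct a uniform wavelength grid
#'
#' The wavelength axis shared by cubes, spectra and models. Wavelengths are
#' always stored in ascending order; an instrument's scan order (the human
#' camera sweeps 900 nm down to 450 nm) is acquisition metadata, not part of
#' the grid.
#'
#' @param start_nm First wavelength in nanometres.
#' @param end_nm Last wavelength in nanometres; must exceed `start_nm`.
#' @param step_nm Grid spacing in nanometres; must divide
#'   `end_nm - start_nm` exactly.
#'
#' @return A `wl_grid` object: list with `start_nm`, `end_nm`, `step_nm` and
#'   the ascending vector `values`.
#'
#' @examples
#' g <- make_grid(450, 900, 5)   # the human acquisition grid, 91 wavelengths
#' length(g$values)
#' @export
make_grid <- function(start_nm, end_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm),
            length(start_nm) == 1, length(end_nm) == 1, length(step_nm) == 1)
  if (!(end_nm > start_nm)) {
    stop("grid error: end_nm must exceed start_nm")
  }
  if (step_nm <= 0) {
    stop("grid error: step_nm must be positive")
  }
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("grid error: step_nm does not divide the range exactly")
  }
  n <- as.integer(round(n_steps)) + 1L
  g <- list(
    start_nm = start_nm,
    end_nm = end_nm,
    step_nm = step_nm,
    values = start_nm + step_nm * (seq_len(n) - 1)
  )
  class(g) <- "wl_grid"
  g
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d wavelengths)\n",
              x$start_nm, x$end_nm, x$step_nm, length(x$values)))
  invisible(x)
}

#' Number of wavelengths in a grid
#' @param grid A `wl_grid`.
#' @return Integer count.
#' @export
grid_length <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  length(grid$values)
}

grids_equal <- function(a, b) {
  inherits(a, "wl_grid") && inherits(b, "wl_grid") &&
    length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) < 1e-9)
}

assert_same_grid <- function(a, b, what = "object") {
  if (!grids_equal(a, b)) {
    stop("grid error: wavelength grids do not match for ", what)
  }
  invisible(TRUE)
}
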