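#' Construct a hyperspectral cube
#'
#' A calibrated reflectance cube: rows x cols x wavelengths, each spatial
#' locus carrying one reflectance spectrum. Values are dimensionless
#' reflectances, non-negative and finite; the third dimension must match the
#' wavelength grid.
#'
#' @param data 3-D numeric array (rows x cols x n_wavelengths).
#' @param grid A `wl_grid` matching `dim(data)[3]`.
#' @param pixel_scale_um Pixel pitch in micrometres; metadata only
#'   (human camera default ~8.3 um).
#' @param subject_id,eye,session Acquisition metadata.
#' @param valid Optional logical matrix (rows x cols); `FALSE` marks pixels
#'   invalidated by registration shifts, excluded from all spatial averages.
#' @param space `"reflectance"` (values must be non-negative) or `"log"`.
#' @return An `hs_cube` object.
#' @export
hs_cube <- function(data, grid, pixel_scale_um = 8.3,
                    subject_id = NA_character_, eye = NA_character_,
                    session = NA_character_, valid = NULL,
                    space = c("reflectance", "log")) {
  space <- match.arg(space)
  stopifnot(is.array(data), length(dim(data)) == 3, inherits(grid, "wl_grid"))
  if (dim(data)[3] != grid_length(grid)) {
    stop("grid error: cube has ", dim(data)[3], " frames but grid has ",
         grid_length(grid), " wavelengths")
  }
  if (!all(is.finite(data))) {
    stop("validation error: cube contains non-finite values")
  }
  if (space == "reflectance" && any(data < 0)) {
    stop("validation error: reflectance values must be >= 0")
  }
  if (!is.null(valid)) {
    stopifnot(is.matrix(valid), is.logical(valid),
              all(dim(valid) == dim(data)[1:2]))
  }
  cube <- list(data = data, grid = grid, pixel_scale_um = pixel_scale_um,
               subject_id = subject_id, eye = eye, session = session,
               valid = valid, space = space)
  class(cube) <- "hs_cube"
  cube
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hs_cube> %d x %d px, %d wavelengths (%g-%g nm) | subject %s\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$end_nm, x$subject_id))
  invisible(x)
}

#' Construct a raw acquisition
#'
#' Uncalibrated camera counts with their dark and white (Spectralon model
#' eye) references. `calibrate_reflectance()` turns this into an [hs_cube()].
#'
#' @param frames 3-D array of raw counts, rows x cols x n_wavelengths.
#' @param dark Dark-current counts: scalar or rows x cols matrix.
#' @param white Per-wavelength white-reference counts (length of grid).
#' @param internal_reflection Per-wavelength internal-reflection offset
#'   counts; defaults to zero.
#' @param grid A `wl_grid`.
#' @return A `raw_acquisition` object.
#' @export
raw_acquisition <- function(frames, dark, white, internal_reflection = 0,
                            grid) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            inherits(grid, "wl_grid"))
  p <- grid_length(grid)
  if (dim(frames)[3] != p) {
    stop("grid error: frames/grid wavelength count mismatch")
  }
  if (length(white) != p) stop("validation error: white must be per-wavelength")
  internal_reflection <- rep_len(internal_reflection, p)
  if (!(is.matrix(dark) || length(dark) == 1)) {
    stop("validation error: dark must be scalar or a 2-D matrix")
  }
  if (any(white <= max(dark))) {
    stop("calibration error: white reference must exceed dark at every wavelength")
  }
  r <- list(frames = frames, dark = dark, white = as.numeric(white),
            internal_reflection = as.numeric(internal_reflection), grid = grid)
  class(r) <- "raw_acquisition"
  r
}

#' Write a cube as a multi-page TIFF
#'
#' Pages are stored in ascending-wavelength order as 32-bit floats. TIFF
#' storage is defined on \[0, 1\], so pages are divided by a scale factor
#' (the cube maximum when it exceeds 1) recorded, together with the grid and
#' metadata, in a JSON sidecar at `<path>.json`; [read_cube()] undoes the
#' scaling, making the round trip lossless to float precision.
#'
#' @param cube An `hs_cube`.
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hs_cube"))
  if (!all(is.finite(cube$data))) {
    stop("validation error: cube contains non-finite values")
  }
  offset <- min(0, min(cube$data))
  scale <- max(max(cube$data) - offset, 1)
  d <- dim(cube$data)
  pages <- lapply(seq_len(d[3]),
                  function(i) matrix((cube$data[, , i] - offset) / scale,
                                     d[1], d[2]))
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("I/O error: could not write TIFF to '", path, "'")
  }
  meta <- list(scale = scale, offset = offset, space = cube$space,
               grid = list(start_nm = cube$grid$start_nm,
                           end_nm = cube$grid$end_nm,
                           step_nm = cube$grid$step_nm),
               pixel_scale_um = cube$pixel_scale_um,
               subject_id = cube$subject_id, eye = cube$eye,
               session = cube$session)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as a cube
#'
#' Pages are stacked along the wavelength axis. When a `<path>.json` sidecar
#' written by [write_cube()] is present its scale factor is applied;
#' otherwise values are taken as stored. Stacks recorded in descending scan
#' order (the human camera) are reversed so wavelengths are always ascending.
#'
#' @param path TIFF file path.
#' @param grid A `wl_grid`; page count must equal the grid length.
#' @param wavelength_order Page order in the file: `"ascending"` (default,
#'   and what [write_cube()] produces) or `"descending"`.
#' @inheritParams hs_cube
#' @return An `hs_cube`.
#' @export
read_cube <- function(path, grid, wavelength_order = c("ascending", "descending"),
                      pixel_scale_um = 8.3, subject_id = NA_character_,
                      eye = NA_character_, session = NA_character_) {
  wavelength_order <- match.arg(wavelength_order)
  stopifnot(inherits(grid, "wl_grid"))
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = FALSE), silent = TRUE)
  if (inherits(pages, "try-error")) {
    stop("format error: '", path, "' is not a readable TIFF file")
  }
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != grid_length(grid)) {
    stop("grid-mismatch error: file has ", length(pages),
         " pages but grid has ", grid_length(grid), " wavelengths")
  }
  if (wavelength_order == "descending") pages <- rev(pages)
  scale <- 1; offset <- 0; space <- "reflectance"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$offset)) offset <- meta$offset
    if (!is.null(meta$space)) space <- meta$space
    if (is.na(subject_id) && !is.null(meta$subject_id)) subject_id <- meta$subject_id
    if (is.na(eye) && !is.null(meta$eye)) eye <- as.character(meta$eye)
    if (is.na(session) && !is.null(meta$session)) session <- as.character(meta$session)
    if (!is.null(meta$pixel_scale_um)) pixel_scale_um <- meta$pixel_scale_um
  }
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # tolerate grey stored with channels
    pg
  })
  d <- dim(pages[[1]])
  data <- array(unlist(pages, use.names = FALSE) * scale + offset,
                dim = c(d[1], d[2], length(pages)))
  hs_cube(data, grid, pixel_scale_um = pixel_scale_um,
          subject_id = subject_id, eye = eye, session = session,
          space = space)
}
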