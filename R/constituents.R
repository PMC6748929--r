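#' Parametric absorbance basis of ocular constituents
#'
#' Unit-norm spectral shapes for the main spectrally active constituents of
#' the eye — ocular media (chiefly the lens), macular pigment, melanin and
#' haemoglobin — plus a short-wavelength amyloid-beta stand-in. The shapes
#' are parametric curves that preserve the qualitative features the analysis
#' exploits (monotone short-wavelength absorbers, the 542/577 nm
#' oxyhaemoglobin double band, macular pigment confined below 550 nm, an
#' amyloid signature concentrated below 565 nm), not digitised literature
#' extinction spectra.
#'
#' Shapes on wavelength lambda (nm):
#' * `ocular_media`: exponential decay `exp(-(lambda - 320)/150)`.
#' * `macular_pigment`: Gaussian band centred 460 nm (sd 35 nm), zero above
#'   550 nm.
#' * `melanin`: power-law decay `lambda^-3`.
#' * `haemoglobin`: sum of Gaussian bands at 542 and 577 nm (sd 12 nm).
#' * `abeta`: logistic step `plogis((565 - lambda)/10)`, high below 565 nm
#'   and negligible above 600 nm.
#'
#' Every column is scaled to unit Euclidean norm on the supplied grid.
#'
#' @param grid A `wl_grid` within 320-900 nm.
#' @return A `constituent_basis`: numeric matrix (n_wavelengths x 5) with
#'   named columns and the grid attached as attribute `grid`.
#' @export
build_constituent_basis <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  if (grid$start_nm < 320 || grid$end_nm > 900) {
    stop("domain error: constituent basis supports 320-900 nm only")
  }
  lambda <- grid$values
  ocular_media <- exp(-(lambda - 320) / 150)
  macular_pigment <- exp(-(lambda - 460)^2 / (2 * 35^2))
  macular_pigment[lambda > 550] <- 0
  melanin <- (lambda / 500)^(-3)
  haemoglobin <- exp(-(lambda - 542)^2 / (2 * 12^2)) +
    exp(-(lambda - 577)^2 / (2 * 12^2))
  abeta <- stats::plogis((565 - lambda) / 10)
  abeta[lambda > 600] <- 0
  B <- cbind(ocular_media = ocular_media,
             macular_pigment = macular_pigment,
             melanin = melanin,
             haemoglobin = haemoglobin,
             abeta = abeta)
  norms <- sqrt(colSums(B^2))
  if (any(norms == 0)) {
    stop("domain error: a constituent has no support on this grid")
  }
  B <- sweep(B, 2, norms, "/")
  attr(B, "grid") <- grid
  class(B) <- c("constituent_basis", class(B))
  B
}
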