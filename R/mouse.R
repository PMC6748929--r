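#' Whole-retina mean spectrum
#'
#' Per-wavelength mean over all non-excluded pixels of a cube — the single
#' reflectance spectrum per retina used by the mouse pipeline, where the
#' small retina makes regional sampling impractical.
#'
#' @param cube An [hs_cube()].
#' @param exclusion_mask Optional `vessel_mask` or logical matrix of pixels
#'   to exclude (vessels, optic nerve head).
#' @return An [hs_spectrum()] with `location_id = "WHOLE"`, in the cube's
#'   space.
#' @export
retina_mean_spectrum <- function(cube, exclusion_mask = NULL) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$data)
  keep <- matrix(TRUE, d[1], d[2])
  if (!is.null(exclusion_mask)) {
    em <- if (inherits(exclusion_mask, "vessel_mask")) exclusion_mask$mask
          else exclusion_mask
    stopifnot(all(dim(em) == d[1:2]))
    keep <- keep & !em
  }
  if (!is.null(cube$valid)) keep <- keep & cube$valid
  if (!any(keep)) stop("sampling error: no pixels retained")
  M <- matrix(cube$data, d[1] * d[2], d[3])
  hs_spectrum(colMeans(M[as.vector(keep), , drop = FALSE]), cube$grid,
              space = cube$space, subject_id = cube$subject_id,
              location_id = "WHOLE", eye = cube$eye, session = cube$session)
}

#' Exclude outlier retinas by the median-absolute-deviation rule
#'
#' At each wavelength the cohort median and (unscaled) median absolute
#' deviation are computed across animals; an animal is flagged at a
#' wavelength when its value is strictly below `median - 3 * MAD`, and
#' excluded when flagged at strictly more than half the wavelengths. With
#' identical spectra the MAD is zero and nothing is excluded (the
#' comparison is strict).
#'
#' @param X Numeric matrix, animals x wavelengths (or list of
#'   [hs_spectrum()]s on a common grid).
#' @param ids Row identifiers (default rownames or indices).
#' @param n_mad MAD multiplier (default 3).
#' @param min_fraction Fraction of wavelengths that must be flagged,
#'   exceeded strictly (default 0.5).
#' @return List with `kept` and `excluded` id vectors, `keep` logical
#'   vector, and the per-animal flagged fraction.
#' @export
exclude_outlier_retinas <- function(X, ids = NULL, n_mad = 3,
                                    min_fraction = 0.5) {
  if (is.list(X) && !is.data.frame(X) && !is.matrix(X)) {
    g <- X[[1]]$grid
    for (s in X) assert_same_grid(s$grid, g, "outlier exclusion")
    if (is.null(ids)) ids <- vapply(X, function(s) s$subject_id, character(1))
    X <- do.call(rbind, lapply(X, function(s) s$values))
  }
  stopifnot(is.matrix(X))
  if (nrow(X) < 3) stop("insufficient-cohort error: need at least 3 retinas")
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X)))
  }
  med <- apply(X, 2, stats::median)
  mad_u <- apply(X, 2, function(v) stats::median(abs(v - stats::median(v))))
  flagged <- sweep(X, 2, med - n_mad * mad_u, "<")
  frac <- rowMeans(flagged)
  keep <- frac <= min_fraction  # excluded only when strictly more than half
  list(kept = ids[keep], excluded = ids[!keep], keep = keep,
       flagged_fraction = frac)
}

#' Compensate inter-session illumination differences
#'
#' For each imaging session the offset is the session's mean control
#' spectrum minus the pooled control mean; that offset is subtracted from
#' every spectrum of the session (log space). Within-session differences —
#' in particular every case-minus-control contrast — are preserved exactly.
#'
#' @param X Numeric matrix, animals x wavelengths, log space.
#' @param session Session label per row.
#' @param is_control Logical per row; every session needs at least one
#'   control.
#' @return The compensated matrix, with the per-session offsets in
#'   attribute `offsets`.
#' @export
compensate_sessions <- function(X, session, is_control) {
  stopifnot(is.matrix(X), length(session) == nrow(X),
            length(is_control) == nrow(X))
  if (!any(is_control)) stop("compensation error: no control animals")
  pooled <- colMeans(X[is_control, , drop = FALSE])
  out <- X
  offsets <- list()
  for (s in unique(session)) {
    in_s <- session == s
    if (!any(in_s & is_control)) {
      stop("compensation error: session '", s, "' has no control animals")
    }
    off <- colMeans(X[in_s & is_control, , drop = FALSE]) - pooled
    out[in_s, ] <- sweep(X[in_s, , drop = FALSE], 2, off)
    offsets[[as.character(s)]] <- off
  }
  attr(out, "offsets") <- offsets
  out
}

#' Run the mouse analysis pipeline
#'
#' Composes the mouse-specific stages: multi-scale vessel + optic-nerve-head
#' segmentation on the 390-460 nm mean image, whole-retina mean spectrum,
#' log transform, linear resampling onto the scoring grid (default
#' 450-680 nm in 5 nm steps), MAD outlier exclusion, inter-session
#' illumination compensation, scoring with the recalibrated human model, and
#' group statistics (t test and ROC/AUC).
#'
#' @param cubes List of mouse [hs_cube()]s (reflectance, mouse grid).
#' @param labels `case` (transgenic) / `control` per cube.
#' @param sessions Imaging-session label per cube.
#' @param human_data Human training [spectrum_matrix()] for recalibration.
#' @param k Removed-axis count for the recalibrated model.
#' @param score_grid Scoring grid (default `make_grid(450, 680, 5)`).
#' @param onh_list Optional list of ONH centres `(row, col)` per cube.
#' @param vessel_band Wavelength range of the segmentation mean image.
#' @param ids Animal identifiers.
#' @param log_floor Reflectance floor before the log.
#' @return List with `scores` (data frame of id, session, label, score),
#'   `excluded` ids, `model` (the recalibrated `dropd_model`), `roc`
#'   (a `roc_result`) and `ttest` (a `ttest_result`).
#' @export
run_mouse_pipeline <- function(cubes, labels, sessions, human_data, k = 2,
                               score_grid = make_grid(450, 680, 5),
                               onh_list = NULL, vessel_band = c(390, 460),
                               ids = NULL, log_floor = 1e-6) {
  n <- length(cubes)
  stopifnot(length(labels) == n, length(sessions) == n)
  if (is.null(ids)) ids <- sprintf("M%02d", seq_len(n))

  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    cube <- cubes[[i]]
    lam <- cube$grid$values
    sel <- which(lam >= vessel_band[1] & lam <= vessel_band[2])
    step <- "vessel segmentation"
    res <- try({
      mean_img <- apply(cube$data[, , sel, drop = FALSE], c(1, 2), mean)
      vm <- segment_vessels_mouse(mean_img,
                                  onh_rc = if (!is.null(onh_list)) onh_list[[i]])
      step <- "retina mean spectrum"
      sp <- retina_mean_spectrum(cube, vm)
      step <- "log transform"
      sp <- log_transform(sp, floor = log_floor)
      step <- "resampling"
      resample_spectrum(sp, score_grid)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      stop("mouse pipeline error at stage '", step, "' for ", ids[i], ": ",
           attr(res, "condition")$message)
    }
    spectra[[i]] <- res
  }
  X <- do.call(rbind, lapply(spectra, function(s) s$values))
  rownames(X) <- ids

  excl <- exclude_outlier_retinas(X, ids = ids)
  X <- X[excl$keep, , drop = FALSE]
  labels_k <- labels[excl$keep]
  sessions_k <- sessions[excl$keep]
  ids_k <- ids[excl$keep]

  X <- compensate_sessions(X, sessions_k, labels_k == "control")
  model <- recalibrate_model(human_data, score_grid, k = k)
  scores <- hs_score(model, X)

  sc_case <- scores[labels_k == "case"]; sc_ctrl <- scores[labels_k == "control"]
  list(scores = data.frame(subject_id = ids_k, session = sessions_k,
                           label = labels_k, score = scores,
                           stringsAsFactors = FALSE),
       excluded = excl$excluded,
       model = model,
       roc = roc_auc(scores, labels_k),
       ttest = ttest_from_summary(x1 = sc_ctrl, x2 = sc_case))
}
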