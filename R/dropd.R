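#' Fit the DROP-D discriminant
#'
#' Dimension Reduction by Orthogonal Projection for Discrimination, in two
#' steps. (1) Within-class variability removal: rows are centred by their
#' class means and the top `k` right singular vectors of the within-class-
#' centred matrix form the removed axes `W` (the nuisance spectra w1, w2,
#' ...). (2) Discrimination: the grand-mean-centred data are deflated onto
#' the orthogonal complement of `span(W)` and the discriminant axis `b` is
#' the principal axis of the between-class scatter of the deflated class
#' means — for two classes, the deflated difference of class means,
#' normalised to unit length. By construction `W' W = I`, `b` is unit norm
#' and orthogonal to every removed axis, so scores are insensitive to any
#' linear combination of the removed within-class axes.
#'
#' Signs are fixed for reproducibility: each column of `W` has its
#' largest-magnitude entry positive, and `b` is oriented so the mean
#' training case score exceeds the mean control score.
#'
#' @param data A [spectrum_matrix()] with both classes present.
#' @param k Number of within-class axes to remove, `0 <= k <= min(n-2, p)`.
#' @return A `dropd_model`: list with `mu` (training mean), `W`
#'   (p x k orthonormal), `b` (unit-norm discriminant axis), `k`, `grid`,
#'   `location_id` and the training class score means.
#' @export
fit_dropd <- function(data, k) {
  stopifnot(inherits(data, "spectrum_matrix"))
  X <- data$X; labels <- data$labels
  n <- nrow(X); p <- ncol(X)
  n_case <- sum(labels == "case"); n_control <- sum(labels == "control")
  if (n_case < 1 || n_control < 1) {
    stop("data error: both classes must be present")
  }
  k_max <- min(n - 2, p)
  if (k < 0 || k > k_max) {
    stop("parameter error: k must be between 0 and ", k_max)
  }

  mu_case <- colMeans(X[labels == "case", , drop = FALSE])
  mu_control <- colMeans(X[labels == "control", , drop = FALSE])
  mu <- colMeans(X)

  if (k > 0) {
    Xw <- X
    Xw[labels == "case", ] <- sweep(X[labels == "case", , drop = FALSE], 2, mu_case)
    Xw[labels == "control", ] <- sweep(X[labels == "control", , drop = FALSE], 2, mu_control)
    W <- svd(Xw, nu = 0, nv = k)$v
    # sign convention: largest-magnitude entry of each column positive
    for (j in seq_len(k)) {
      i_max <- which.max(abs(W[, j]))
      if (W[i_max, j] < 0) W[, j] <- -W[, j]
    }
  } else {
    W <- matrix(0, p, 0)
  }

  d <- mu_case - mu_control
  d_defl <- if (k > 0) d - W %*% crossprod(W, d) else d
  d_defl <- as.numeric(d_defl)
  nrm <- sqrt(sum(d_defl^2))
  if (nrm < 1e-12) {
    stop("data error: class means indistinguishable after deflation")
  }
  b <- d_defl / nrm

  model <- list(mu = mu, W = W, b = b, k = k, grid = data$grid,
                location_id = if (!is.null(data$metadata))
                  data$metadata$location[1] else NA_character_,
                train_case_mean = sum((mu_case - mu) * b),
                train_control_mean = sum((mu_control - mu) * b),
                n_case = n_case, n_control = n_control)
  class(model) <- "dropd_model"
  model
}

#' @export
print.dropd_model <- function(x, ...) {
  cat(sprintf("<dropd_model> %d wavelengths, k = %d removed axes | location %s\n",
              length(x$b), x$k, x$location_id))
  invisible(x)
}

#' Hyperspectral (HS) score of a spectrum
#'
#' The HS score is the inner product of the mean-centred spectrum with the
#' discriminant axis: `score = (x - mu) . b`. Because `b` is orthogonal to
#' the removed within-class axes, explicit deflation of `x` is unnecessary.
#'
#' @param model A `dropd_model`.
#' @param x An [hs_spectrum()] in log space, a numeric vector on the model
#'   grid, or a matrix (rows scored independently).
#' @return Numeric score(s).
#' @export
hs_score <- function(model, x) {
  stopifnot(inherits(model, "dropd_model"))
  if (inherits(x, "hs_spectrum")) {
    assert_same_grid(x$grid, model$grid, "scoring")
    if (x$space != "log") stop("validation error: scoring requires log space")
    x <- x$values
  }
  if (is.matrix(x)) {
    if (ncol(x) != length(model$b)) stop("grid error: wrong spectrum length")
    return(as.numeric(sweep(x, 2, model$mu) %*% model$b))
  }
  if (length(x) != length(model$b)) stop("grid error: wrong spectrum length")
  sum((x - model$mu) * model$b)
}

#' Choose the number of removed axes by leave-one-out cross-validation
#'
#' For each candidate `k`, every subject is held out in turn, the model is
#' fitted on the remainder and the held-out spectrum is scored; the
#' criterion is the AUC of the held-out scores against the group labels.
#' The chosen `k` maximises the criterion, with ties broken towards the
#' smallest `k` (parsimony).
#'
#' @param data A [spectrum_matrix()] with `n >= 4` and at least 2 per class.
#' @param k_max Largest `k` considered; clipped (with a warning) to `n - 3`
#'   so every leave-one-out fit is feasible.
#' @return A `cv_curve`: data frame of `k` and `auc`, plus `chosen_k`,
#'   the held-out scores at `chosen_k`, and `informative` (`FALSE` when no
#'   `k` beats chance by more than two binomial standard errors, as with
#'   permuted labels).
#' @export
select_k_loocv <- function(data, k_max = 10) {
  stopifnot(inherits(data, "spectrum_matrix"))
  X <- data$X; labels <- data$labels
  n <- nrow(X)
  if (n < 4 || sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("data error: need n >= 4 with at least 2 subjects per class")
  }
  hard_max <- n - 3  # leave-one-out fit uses n-1 rows, k <= (n-1) - 2
  if (k_max > hard_max) {
    warning("k_max clipped to ", hard_max)
    k_max <- hard_max
  }
  ks <- 0:k_max
  held_scores <- matrix(NA_real_, n, length(ks))
  for (i in seq_len(n)) {
    sub <- spectrum_matrix(X[-i, , drop = FALSE], labels[-i], data$grid)
    for (j in seq_along(ks)) {
      m <- fit_dropd(sub, ks[j])
      held_scores[i, j] <- hs_score(m, X[i, ])
    }
  }
  aucs <- vapply(seq_along(ks), function(j) {
    auc_mann_whitney(held_scores[, j], labels)
  }, numeric(1))
  best <- max(aucs)
  chosen <- ks[which(aucs >= best - 1e-12)[1]]
  n1 <- sum(labels == "case"); n2 <- sum(labels == "control")
  se_null <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))  # null SD of the AUC
  res <- list(curve = data.frame(k = ks, auc = aucs), chosen_k = chosen,
              held_out_scores = held_scores[, which(ks == chosen)],
              labels = labels,
              informative = best > 0.5 + 2 * se_null)
  class(res) <- "cv_curve"
  res
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> chosen k = %d (held-out AUC %.3f)%s\n",
              x$chosen_k, max(x$curve$auc),
              if (!x$informative) " [no k beats chance]" else ""))
  invisible(x)
}

#' Decompose a spectral axis into ocular constituents
#'
#' Ordinary least squares of a unit-norm spectral axis (a removed
#' within-class axis or the discriminant axis) on a subset of constituent
#' basis columns plus an intercept. The fit quality is reported as
#' `rmse_percent = 100 * sqrt(mean(residual^2))`, the scale on which
#' sub-percent residuals indicate the axis is essentially a constituent
#' mixture.
#'
#' @param axis Numeric vector (typically unit norm) on the basis grid, or an
#'   [hs_spectrum()].
#' @param basis A [build_constituent_basis()] matrix.
#' @param include Character subset of basis columns (default: the four
#'   nuisance constituents).
#' @return A `constituent_fit`: coefficients, intercept, `rmse_percent`,
#'   fitted values and residual.
#' @export
fit_constituents <- function(axis, basis,
                             include = c("ocular_media", "macular_pigment",
                                         "melanin", "haemoglobin")) {
  if (inherits(axis, "hs_spectrum")) {
    assert_same_grid(axis$grid, attr(basis, "grid"), "constituent fit")
    axis <- axis$values
  }
  stopifnot(length(axis) == nrow(basis), all(include %in% colnames(basis)))
  A <- cbind(intercept = 1, basis[, include, drop = FALSE])
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    warning("condition warning: rank-deficient basis; minimum-norm solution used")
    coefs <- as.numeric(MASS::ginv(A) %*% axis)
  } else {
    coefs <- qr.coef(qr_A, axis)
  }
  names(coefs) <- colnames(A)
  fitted <- as.numeric(A %*% coefs)
  resid <- axis - fitted
  res <- list(coefficients = coefs[include], intercept = coefs[["intercept"]],
              rmse_percent = 100 * sqrt(mean(resid^2)),
              fitted = fitted, residual = resid)
  class(res) <- "constituent_fit"
  res
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation of the values onto `new_grid`, which must lie
#' within the range of the current grid (no extrapolation).
#'
#' @param spectrum An [hs_spectrum()] or numeric vector with `grid`.
#' @param new_grid Target `wl_grid`.
#' @param grid Current grid when `spectrum` is a bare vector.
#' @return Resampled object of the same type.
#' @export
resample_spectrum <- function(spectrum, new_grid, grid = NULL) {
  stopifnot(inherits(new_grid, "wl_grid"))
  if (inherits(spectrum, "hs_spectrum")) {
    grid <- spectrum$grid
    v <- spectrum$values
  } else {
    stopifnot(inherits(grid, "wl_grid"))
    v <- spectrum
  }
  if (new_grid$start_nm < grid$start_nm - 1e-9 ||
      new_grid$end_nm > grid$end_nm + 1e-9) {
    stop("range error: new grid extends beyond the spectrum's range")
  }
  out <- stats::approx(grid$values, v, xout = new_grid$values,
                       method = "linear", rule = 1)$y
  if (inherits(spectrum, "hs_spectrum")) {
    hs_spectrum(out, new_grid, space = spectrum$space,
                subject_id = spectrum$subject_id,
                location_id = spectrum$location_id,
                eye = spectrum$eye, session = spectrum$session)
  } else {
    out
  }
}

#' Recalibrate a model to a different wavelength range
#'
#' Refits the discriminant after resampling the training spectra onto a new
#' grid — the adjustment needed to apply a model trained on one imaging
#' system (human, 450-900 nm) to data from another with a narrower range
#' (mouse, 450-680 nm).
#'
#' @param data The training [spectrum_matrix()].
#' @param new_grid Target `wl_grid`, within the training grid's range.
#' @param k Number of removed axes, or `NULL` to re-select by
#'   [select_k_loocv()].
#' @param k_max Passed to [select_k_loocv()] when `k` is `NULL`.
#' @return A `dropd_model` on `new_grid`.
#' @export
recalibrate_model <- function(data, new_grid, k = NULL, k_max = 10) {
  stopifnot(inherits(data, "spectrum_matrix"), inherits(new_grid, "wl_grid"))
  if (grids_equal(data$grid, new_grid)) {
    newdata <- data
  } else {
    if (new_grid$start_nm < data$grid$start_nm - 1e-9 ||
        new_grid$end_nm > data$grid$end_nm + 1e-9) {
      stop("range error: new grid extends beyond the training grid")
    }
    Xn <- t(apply(data$X, 1, function(v)
      resample_spectrum(v, new_grid, grid = data$grid)))
    newdata <- spectrum_matrix(Xn, data$labels, new_grid,
                               metadata = data$metadata)
  }
  if (is.null(k)) k <- select_k_loocv(newdata, k_max)$chosen_k
  fit_dropd(newdata, k)
}

#' Append per-subject overall scores
#'
#' Adds `overall` rows to an HS score table: for each subject (and eye), the
#' arithmetic mean of the scores at the six retinal sampling locations.
#'
#' @param table Data frame with columns `subject_id`, `eye`, `location_id`,
#'   `score`, `label`; every subject must have all six locations.
#' @param locations The locations averaged (default `F1,F2,S1,S2,I1,I2`).
#' @return The table with `overall` rows appended.
#' @export
aggregate_scores <- function(table,
                             locations = c("F1", "F2", "S1", "S2", "I1", "I2")) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "eye", "location_id", "score", "label") %in%
                  names(table)))
  base <- table[table$location_id %in% locations, ]
  keys <- unique(base[, c("subject_id", "eye")])
  missing <- character(0)
  overall <- NULL
  for (i in seq_len(nrow(keys))) {
    rows <- base[base$subject_id == keys$subject_id[i] &
                   base$eye == keys$eye[i], ]
    if (!setequal(rows$location_id, locations) ||
        nrow(rows) != length(locations)) {
      missing <- c(missing, keys$subject_id[i])
      next
    }
    overall <- rbind(overall, data.frame(
      subject_id = keys$subject_id[i], eye = keys$eye[i],
      location_id = "overall", score = mean(rows$score),
      label = rows$label[1], stringsAsFactors = FALSE))
  }
  if (length(missing) > 0) {
    stop("aggregation error: subjects missing locations: ",
         paste(unique(missing), collapse = ", "))
  }
  rbind(table, overall)
}
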