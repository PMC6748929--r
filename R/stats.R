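#' Two-sample t test from summary statistics or raw samples
#'
#' Unpaired two-tailed t test reporting the difference between means
#' (`mean2 - mean1`) with its 95% confidence interval, as in a cohort
#' demographics table. The pooled-variance form is the default; Welch's
#' unequal-variance form is available via `variant`.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries (`n >= 2`, `sd >= 0`).
#'   Alternatively pass raw samples via `x1`/`x2`.
#' @param x1,x2 Optional raw samples; when given, summaries are computed
#'   from them.
#' @param variant `"pooled"` or `"welch"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `ttest_result`: `mean_diff`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p`, `variant`.
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                               x1 = NULL, x2 = NULL,
                               variant = c("pooled", "welch"),
                               conf_level = 0.95) {
  variant <- match.arg(variant)
  if (!is.null(x1) || !is.null(x2)) {
    stopifnot(!is.null(x1), !is.null(x2))
    n1 <- length(x1); mean1 <- mean(x1); sd1 <- stats::sd(x1)
    n2 <- length(x2); mean2 <- mean(x2); sd2 <- stats::sd(x2)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  diff <- mean2 - mean1
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2) * sqrt(1 / n1 + 1 / n2)
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    t_stat <- if (diff == 0) NaN else sign(diff) * Inf
    p <- if (diff == 0) NaN else 0
  } else {
    t_stat <- diff / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  half <- stats::qt(1 - (1 - conf_level) / 2, df) * se
  res <- list(mean_diff = diff, ci_low = diff - half, ci_high = diff + half,
              t = t_stat, df = df, p = p, variant = variant,
              n1 = n1, n2 = n2)
  class(res) <- "ttest_result"
  res
}

#' Odds ratio and chi-square test for a 2x2 table
#'
#' `OR = (a*d) / (b*c)` for the table `rbind(c(a, b), c(c, d))` with rows =
#' groups and columns = (event, non-event); the orientation (which category
#' is the event and which group is the numerator) is the caller's explicit
#' choice and is echoed in the result. The 95% CI is the Woolf log method,
#' `exp(log(OR) +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`; the chi-square
#' statistic is the standard margin formula without continuity correction.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a`/`b` events and
#'   non-events in the numerator group, `c`/`d` in the reference group.
#' @param orientation Optional character description of the event category
#'   and numerator group, carried through to the result.
#' @return An `odds_ratio_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `chi2`, `p`, `orientation`. With a zero cell the CI is `NA` (flagged,
#'   no continuity correction is applied).
#' @export
odds_ratio_2x2 <- function(a, b, c, d, orientation = NULL) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  or <- (a * d) / (b * c)
  if (all(cells > 0)) {
    se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  n <- sum(cells)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- if (denom == 0) NaN else n * (a * d - b * c)^2 / denom
  p <- if (is.nan(chi2)) NaN else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  res <- list(odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
              chi2 = chi2, p = p, orientation = orientation)
  class(res) <- "odds_ratio_result"
  res
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation; 95% CI by the Fisher z transform
#' (`tanh(atanh(r) +- 1.96/sqrt(n - 3))`) and two-tailed p value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`, non-constant.
#' @return A `correlation_result`: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("validation error: need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant input")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  res <- list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n)
  class(res) <- "correlation_result"
  res
}

# AUC as the Mann-Whitney statistic (ties counted 1/2), cases scored high.
auc_mann_whitney <- function(scores, labels) {
  pos <- labels == "case"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("validation error: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve and AUC for HS scores
#'
#' AUC computed as the Mann-Whitney statistic over all case-control pairs
#' (ties counted one half), with `case` as the positive, high-scoring class.
#' The 95% CI uses the Hanley-McNeil variance by default or a stratified
#' bootstrap; the p value against AUC = 0.5 uses the normal approximation
#' with the null (mid-rank) variance.
#'
#' @param scores Numeric scores.
#' @param labels `case`/`control` per score.
#' @param ci_method `"hanley"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `p`, and the ROC
#'   `points` (data frame of `fpr`, `tpr`, monotone non-decreasing).
#' @export
roc_auc <- function(scores, labels, ci_method = c("hanley", "bootstrap"),
                    n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  labels <- as.character(labels)
  pos <- labels == "case"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("validation error: both classes required")
  auc <- auc_mann_whitney(scores, labels)

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thresholds, function(th) {
    c(fpr = sum(scores[!pos] >= th) / n2, tpr = sum(scores[pos] >= th) / n1)
  }, c(fpr = 0, tpr = 0)))
  points <- data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"])

  if (ci_method == "hanley") {
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n2 - 1) * (q2 - auc^2)) / (n1 * n2)
    se <- sqrt(max(v, 0))
    ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  } else {
    boots <- vapply(seq_len(n_boot), function(i) {
      i1 <- sample(which(pos), n1, replace = TRUE)
      i2 <- sample(which(!pos), n2, replace = TRUE)
      auc_mann_whitney(c(scores[i1], scores[i2]),
                       c(labels[i1], labels[i2]))
    }, numeric(1))
    ci <- as.numeric(stats::quantile(boots, c(0.025, 0.975), names = FALSE))
  }
  se_null <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  p <- 2 * stats::pnorm(-abs(auc - 0.5) / se_null)
  res <- list(auc = auc, ci_low = ci[1], ci_high = ci[2], p = p,
              points = points, n_case = n1, n_control = n2)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f, p = %.3g)\n",
              x$auc, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Benjamini-Yekutieli false discovery rate control
#'
#' Step-up procedure valid under arbitrary dependence: reject the `i`
#' smallest p values for all `i <= i*`, where
#' `i* = max{ i : p_(i) <= i * q / (m * c(m)) }` and
#' `c(m) = sum_{j=1}^m 1/j`.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param q Target FDR level (default 0.05).
#' @return An `fdr_result`: data frame `table` with the input p values and
#'   rejection flags (input order), plus `n_rejected` and `q`.
#' @export
by_fdr <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), q > 0)
  m <- length(pvalues)
  ord <- order(pvalues)
  cm <- sum(1 / seq_len(m))
  thresh <- seq_len(m) * q / (m * cm)
  ok <- which(pvalues[ord] <= thresh)
  rejected <- rep(FALSE, m)
  if (length(ok) > 0) rejected[ord[seq_len(max(ok))]] <- TRUE
  res <- list(table = data.frame(p = pvalues, rejected = rejected),
              n_rejected = sum(rejected), q = q)
  class(res) <- "fdr_result"
  res
}

#' Group main effect of a two-way repeated-measures ANOVA
#'
#' Mixed design with group (case/control) as the between-subjects factor
#' and retinal location as the within-subjects factor, balanced on
#' location. The group main effect is tested against the subjects-within-
#' groups stratum: `F = MS_group / MS_subjects_within_group` on
#' `(1, n - 2)` degrees of freedom for two groups.
#'
#' @param table HS score table: data frame with `subject_id`,
#'   `location_id`, `score`, `label`; every subject must have a score at
#'   every location (no imputation).
#' @param locations Within-subject levels used (default the six sampling
#'   regions).
#' @return An `anova_result`: `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_group_effect <- function(table,
                                  locations = c("F1", "F2", "S1", "S2",
                                                "I1", "I2")) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "location_id", "score", "label") %in%
                  names(table)))
  tab <- table[table$location_id %in% locations, ]
  counts <- table(tab$subject_id)
  if (any(counts != length(locations))) {
    stop("data error: missing cells for subject(s): ",
         paste(names(counts)[counts != length(locations)], collapse = ", "))
  }
  L <- length(locations)
  subj <- unique(tab$subject_id)
  n <- length(subj)
  subj_mean <- tapply(tab$score, tab$subject_id, mean)
  subj_label <- tapply(tab$label, tab$subject_id, function(l) l[1])
  groups <- unique(subj_label)
  if (length(groups) != 2) stop("data error: exactly two groups required")
  grand <- mean(tab$score)
  group_means <- tapply(subj_mean, subj_label, mean)
  n_per_group <- table(subj_label)

  ss_group <- L * sum(n_per_group * (group_means - grand)^2)
  ss_subj_within <- L * sum((subj_mean - group_means[subj_label])^2)
  df1 <- length(groups) - 1
  df2 <- n - length(groups)
  f_stat <- (ss_group / df1) / (ss_subj_within / df2)
  res <- list(F = f_stat, df1 = df1, df2 = df2,
              p = stats::pf(f_stat, df1, df2, lower.tail = FALSE))
  class(res) <- "anova_result"
  res
}
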