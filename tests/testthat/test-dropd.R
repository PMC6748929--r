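test_that("fitted models satisfy the orthogonality invariants for every k", {
  sim <- small_cohort(seed = 1)
  for (k in c(0, 1, 2, 4)) {
    m <- fit_dropd(sim$spectra, k)
    expect_equal(m$k, k)
    expect_equal(sqrt(sum(m$b^2)), 1, tolerance = 1e-12)
    if (k > 0) {
      expect_lt(max(abs(crossprod(m$W) - diag(k))), 1e-10)
      expect_lt(max(abs(crossprod(m$W, m$b))), 1e-10)
    }
    # sign convention: training cases score above controls
    expect_gt(m$train_case_mean, m$train_control_mean)
  }
  expect_error(fit_dropd(sim$spectra, 100), "parameter error")
  one_class <- spectrum_matrix(sim$spectra$X, rep("case", nrow(sim$spectra$X)),
                               sim$spectra$grid)
  expect_error(fit_dropd(one_class, 0), "both classes")
})

test_that("k = 0 axis equals the brute-force centred class-mean difference", {
  sim <- small_cohort(seed = 2)
  m <- fit_dropd(sim$spectra, 0)
  X <- sim$spectra$X; lab <- sim$spectra$labels
  d <- colMeans(X[lab == "case", ]) - colMeans(X[lab == "control", ])
  d <- d / sqrt(sum(d^2))
  expect_gte(sum(m$b * d), 1 - 1e-10)
})

test_that("scores are inner products, insensitive to removed axes", {
  sim <- small_cohort(seed = 3)
  m <- fit_dropd(sim$spectra, 3)
  # centring: the training mean scores zero
  expect_equal(hs_score(m, m$mu), 0)
  set.seed(5)
  for (r in 1:10) {
    x <- rnorm(length(m$b))
    alpha <- rnorm(1, sd = 10)
    j <- sample(3, 1)
    expect_equal(hs_score(m, x + alpha * m$W[, j]), hs_score(m, x),
                 tolerance = 1e-9 * max(1, abs(alpha)))
    t_shift <- rnorm(1)
    expect_equal(hs_score(m, x + t_shift * m$b), hs_score(m, x) + t_shift,
                 tolerance = 1e-9)
  }
  expect_error(hs_score(m, rnorm(10)), "grid error")
})

test_that("deflation is idempotent", {
  sim <- small_cohort(seed = 4)
  m <- fit_dropd(sim$spectra, 2)
  X <- sweep(sim$spectra$X, 2, m$mu)
  P <- diag(ncol(X)) - m$W %*% t(m$W)
  once <- X %*% P
  twice <- once %*% P
  expect_lt(max(abs(twice - once)), 1e-12 * max(abs(once)))
})

test_that("LOO selects the planted nuisance dimensionality", {
  # two dominant nuisance axes -> k = 2
  sim2 <- small_cohort(seed = 6)
  cv2 <- select_k_loocv(sim2$spectra, k_max = 4)
  expect_equal(cv2$chosen_k, 2)
  expect_true(cv2$informative)
  # pure signal + noise -> k = 0
  sim0 <- simulate_cohort(n_case = 20, n_control = 20, effect_size = 12,
                          noise_sd = 0.02, seed = 7,
                          nuisance_sds = c(ocular_media = 0, macular_pigment = 0,
                                           melanin = 0, haemoglobin = 0))
  cv0 <- select_k_loocv(sim0$spectra, k_max = 3)
  expect_equal(cv0$chosen_k, 0)
  # permuted labels: no k beats chance, flagged
  set.seed(8)
  perm <- spectrum_matrix(sim2$spectra$X, sample(sim2$spectra$labels),
                          sim2$spectra$grid)
  cv_perm <- select_k_loocv(perm, k_max = 3)
  expect_false(cv_perm$informative)
  # no k beats chance by more than two null SDs (LOO bias can push the
  # held-out AUC below 0.5, never meaningfully above it)
  se_null <- sqrt((20 + 20 + 1) / (12 * 20 * 20))
  expect_true(all(cv_perm$curve$auc <= 0.5 + 2 * se_null))
  expect_warning(select_k_loocv(sim0$spectra, k_max = 50), "clipped")
})

test_that("recovered axis aligns with the deflated planted signature", {
  sim <- simulate_cohort(n_case = 40, n_control = 40, effect_size = 12,
                         noise_sd = 0.02, seed = 11,
                         nuisance_sds = c(ocular_media = 0, macular_pigment = 0,
                                          melanin = 2.4, haemoglobin = 2.4))
  m <- fit_dropd(sim$spectra, 2)
  beta <- sim$truth$beta
  bd <- beta - m$W %*% crossprod(m$W, beta)
  bd <- bd / sqrt(sum(bd^2))
  expect_gte(abs(sum(m$b * bd)), 0.9)
})

test_that("constituent fits recover mixtures and report residual RMSE", {
  g <- human_grid()
  B <- build_constituent_basis(g)
  # an axis equal to one basis column: coefficient 1, zero residual
  fit1 <- fit_constituents(B[, "melanin"], B)
  expect_equal(unname(fit1$coefficients["melanin"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit1$coefficients[c("ocular_media", "macular_pigment",
                                          "haemoglobin")]),
               rep(0, 3), tolerance = 1e-8)
  expect_lt(fit1$rmse_percent, 1e-8)
  # axis orthogonal to basis + intercept: residual equals projection oracle
  A <- cbind(1, B[, c("ocular_media", "macular_pigment", "melanin",
                      "haemoglobin")])
  set.seed(13)
  v <- rnorm(nrow(B))
  v_orth <- v - A %*% solve(crossprod(A), crossprod(A, v))
  v_orth <- v_orth / sqrt(sum(v_orth^2))
  fit2 <- fit_constituents(as.numeric(v_orth), B)
  expect_equal(fit2$rmse_percent, 100 * sqrt(mean(v_orth^2)), tolerance = 1e-6)
  # planted mixture + small residual: coefficients recovered within 3 SE,
  # residual RMSE at the planted 0.4% scale
  truth_coef <- c(ocular_media = 0.6, melanin = 0.7, haemoglobin = 0.3)
  set.seed(14)
  w1 <- as.numeric(B[, names(truth_coef)] %*% truth_coef + rnorm(nrow(B), sd = 0.004))
  fit3 <- fit_constituents(w1, B)
  A3 <- cbind(1, B[, c("ocular_media", "macular_pigment", "melanin",
                       "haemoglobin")])
  sigma2 <- sum(fit3$residual^2) / (nrow(B) - ncol(A3))
  se <- sqrt(diag(sigma2 * solve(crossprod(A3))))[-1]
  names(se) <- c("ocular_media", "macular_pigment", "melanin", "haemoglobin")
  for (nm in names(truth_coef)) {
    expect_lt(abs(fit3$coefficients[[nm]] - truth_coef[[nm]]), 3 * se[[nm]])
  }
  expect_lt(abs(fit3$rmse_percent - 0.4), 0.12)
  # rank-deficient basis: warned, still a least-squares solution
  B2 <- cbind(B, dup = B[, "melanin"])
  attr(B2, "grid") <- g
  expect_warning(fit_constituents(w1, B2, include = c("melanin", "dup")),
                 "condition warning")
})

test_that("spectra resample linearly onto subranges", {
  g1 <- make_grid(320, 680, 1)
  v <- 0.5 + 0.001 * (g1$values - 320)  # linear in wavelength
  g2 <- make_grid(450, 680, 5)
  out <- resample_spectrum(v, g2, grid = g1)
  expect_equal(length(out), 47)
  expect_equal(out, 0.5 + 0.001 * (g2$values - 320), tolerance = 1e-12)
  s <- hs_spectrum(v, g1, subject_id = "M1")
  same <- resample_spectrum(s, g1)
  expect_equal(same$values, s$values)
  expect_error(resample_spectrum(s, make_grid(300, 600, 5)), "range error")
})

test_that("recalibration restricts the model without losing discrimination", {
  sim <- small_cohort(seed = 16)
  m_full <- fit_dropd(sim$spectra, 2)
  m_same <- recalibrate_model(sim$spectra, sim$spectra$grid, k = 2)
  expect_equal(m_same$b, m_full$b)
  expect_equal(m_same$W, m_full$W)
  sub <- make_grid(450, 680, 5)
  m_sub <- recalibrate_model(sim$spectra, sub, k = 2)
  expect_equal(length(m_sub$b), 47)
  expect_error(recalibrate_model(sim$spectra, make_grid(400, 700, 5), k = 2),
               "range error")
})

test_that("overall scores are per-subject means over the six locations", {
  locs <- c("F1", "F2", "S1", "S2", "I1", "I2")
  tab <- expand.grid(subject_id = c("A", "B"), location_id = locs,
                     stringsAsFactors = FALSE)
  tab$eye <- "study"
  tab$label <- ifelse(tab$subject_id == "A", "case", "control")
  tab$score <- ifelse(tab$subject_id == "A", 2, seq_len(nrow(tab)) %% 6 + 1)
  tab$score[tab$subject_id == "B"] <- 1:6
  agg <- aggregate_scores(tab)
  ov <- agg[agg$location_id == "overall", ]
  expect_equal(ov$score[ov$subject_id == "A"], 2)
  expect_equal(ov$score[ov$subject_id == "B"], 3.5)
  # permutation of location order changes nothing
  agg2 <- aggregate_scores(tab[sample(nrow(tab)), ])
  ov2 <- agg2[agg2$location_id == "overall", ]
  expect_equal(sort(ov2$score), sort(ov$score))
  expect_error(aggregate_scores(tab[tab$location_id != "F1" |
                                      tab$subject_id != "A", ]),
               "aggregation error.*A")
})
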