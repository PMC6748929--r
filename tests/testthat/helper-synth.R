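# Shared fixtures and independent oracles, built in code at test time.

human_grid <- function() make_grid(450, 900, 5)

tiny_grid <- function() make_grid(450, 680, 10)  # 24 wavelengths

# Small labelled cohort with planted structure, for discriminant tests.
small_cohort <- function(seed = 1, n = 20, effect = 12, noise = 0.02,
                         nuisance = c(ocular_media = 0, macular_pigment = 0,
                                      melanin = 10 * 12 * 0.02,
                                      haemoglobin = 10 * 12 * 0.02)) {
  simulate_cohort(n_case = n, n_control = n, effect_size = effect,
                  noise_sd = noise, nuisance_sds = nuisance, seed = seed)
}

# Constant-spectrum cube with a known per-wavelength profile.
flat_cube <- function(profile, nr = 8, nc = 8, grid = NULL) {
  if (is.null(grid)) grid <- make_grid(450, 450 + 5 * (length(profile) - 1), 5)
  hs_cube(array(rep(profile, each = nr * nc), c(nr, nc, length(profile))), grid)
}

# Brute-force Savitzky-Golay: per-point local least-squares polynomial fit,
# terminal half-windows evaluated from the first/last full window.
savgol_brute <- function(y, order, window) {
  n <- length(y); h <- (window - 1) / 2
  out <- numeric(n)
  fit_window <- function(idx, eval_at) {
    x <- idx - mean(idx)
    co <- stats::lm.fit(outer(x, 0:order, "^"), y[idx])$coefficients
    sum(co * (eval_at - mean(idx))^(0:order))
  }
  for (i in seq_len(n)) {
    idx <- if (i <= h) 1:window else if (i > n - h) (n - window + 1):n
           else (i - h):(i + h)
    out[i] <- fit_window(idx, i)
  }
  out
}

# O(n^2) pairwise AUC oracle (ties counted one half).
auc_brute <- function(scores, labels) {
  cs <- scores[labels == "case"]; ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Direct evaluation of the Benjamini-Yekutieli definition.
by_brute <- function(p, q) {
  m <- length(p); ord <- order(p)
  cm <- sum(1 / seq_len(m))
  ok <- which(p[ord] <= seq_len(m) * q / (m * cm))
  rej <- rep(FALSE, m)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}
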