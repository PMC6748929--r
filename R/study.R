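#' Default configuration for a synthetic human study
#'
#' Study conditions mirroring the human cohorts: a principal cohort of
#' 15 cases / 20 controls whose study eyes train the model, fellow-eye
#' repeat acquisitions of the same subjects, and an independent validation
#' cohort of 4 cases / 13 controls.
#'
#' @param seed Master seed; all per-location and per-cohort seeds derive
#'   from it.
#' @param n_case,n_control Principal cohort sizes.
#' @param n_validation_case,n_validation_control Validation cohort sizes.
#' @param effect_size,noise_sd,nuisance_sds Generative parameters, see
#'   [simulate_cohort()].
#' @param k_max Largest removed-axis count considered by LOO selection.
#' @param grid Acquisition grid.
#' @return Named list of configuration values.
#' @export
human_study_config <- function(seed = 1, n_case = 15, n_control = 20,
                               n_validation_case = 4,
                               n_validation_control = 13,
                               effect_size = 1.3, noise_sd = 0.02,
                               nuisance_sds = default_nuisance_sds(),
                               k_max = 5, grid = make_grid(450, 900, 5)) {
  list(seed = seed, n_case = n_case, n_control = n_control,
       n_validation_case = n_validation_case,
       n_validation_control = n_validation_control,
       effect_size = effect_size, noise_sd = noise_sd,
       nuisance_sds = nuisance_sds, k_max = k_max, grid = grid,
       locations = c("F1", "F2", "S1", "S2", "I1", "I2"))
}

#' Run the full human study on synthetic cohorts
#'
#' End-to-end reproduction of the human analysis at the cohort-spectra
#' level: for each of the six sampling locations a principal cohort is
#' simulated (foveal locations include macular-pigment loading), the
#' removed-axis count is chosen by leave-one-out cross-validation, the
#' DROP-D model is fitted and applied to the study eyes (held-out LOO
#' scores), to fellow-eye re-acquisitions of the same subjects, and to an
#' independent validation cohort. Scores are aggregated into per-subject
#' overall means and the study statistics are computed: per-location t
#' tests with Benjamini-Yekutieli correction, the repeated-measures group
#' effect, ROC/AUC per cohort, and the study-vs-fellow-eye score
#' correlation.
#'
#' The pipeline is deterministic in the configuration: the same `seed`
#' reproduces every score and statistic exactly.
#'
#' @param config A [human_study_config()].
#' @param out_dir Optional directory; when given, score tables and a JSON
#'   statistics report are written there.
#' @return List with `score_table` (study + fellow + validation rows, with
#'   overall), `models`, `cv_curves`, and `stats`.
#' @export
run_human_study <- function(config = human_study_config(), out_dir = NULL) {
  locs <- config$locations
  models <- list(); cv_curves <- list()
  tabs <- list()
  loo_scores <- list()

  for (li in seq_along(locs)) {
    loc <- locs[li]
    loc_seed <- config$seed + 1000L * li
    foveal <- loc %in% c("F1", "F2")
    principal <- simulate_cohort(
      n_case = config$n_case, n_control = config$n_control,
      effect_size = config$effect_size, nuisance_sds = config$nuisance_sds,
      noise_sd = config$noise_sd, grid = config$grid, seed = loc_seed,
      foveal = foveal, location_id = loc)
    fellow <- simulate_cohort(
      effect_size = config$effect_size, nuisance_sds = config$nuisance_sds,
      noise_sd = config$noise_sd, grid = config$grid, seed = loc_seed + 7L,
      foveal = foveal, location_id = loc, truth = principal$truth)
    validation <- simulate_cohort(
      n_case = config$n_validation_case,
      n_control = config$n_validation_control,
      effect_size = config$effect_size, nuisance_sds = config$nuisance_sds,
      noise_sd = config$noise_sd, grid = config$grid, seed = loc_seed + 13L,
      foveal = foveal, location_id = loc)

    cv <- select_k_loocv(principal$spectra, k_max = config$k_max)
    model <- fit_dropd(principal$spectra, cv$chosen_k)
    models[[loc]] <- model
    cv_curves[[loc]] <- cv
    loo_scores[[loc]] <- cv$held_out_scores

    mk_tab <- function(sm, eye, scores) {
      data.frame(subject_id = paste0(eye, "_", sm$metadata$subject_id),
                 eye = eye, location_id = loc, score = scores,
                 label = sm$labels, stringsAsFactors = FALSE)
    }
    tabs[[length(tabs) + 1]] <- mk_tab(principal$spectra, "study",
                                       hs_score(model, principal$spectra$X))
    tabs[[length(tabs) + 1]] <- mk_tab(fellow$spectra, "fellow",
                                       hs_score(model, fellow$spectra$X))
    tabs[[length(tabs) + 1]] <- mk_tab(validation$spectra, "validation",
                                       hs_score(model, validation$spectra$X))
  }
  score_table <- do.call(rbind, tabs)
  score_table <- aggregate_scores(score_table)

  # Per-location group contrasts on held-out (LOO) study-eye scores,
  # BY-corrected across locations.
  principal_labels <- rep(c("case", "control"),
                          c(config$n_case, config$n_control))
  loc_tests <- lapply(locs, function(loc) {
    s <- loo_scores[[loc]]
    ttest_from_summary(x1 = s[principal_labels == "control"],
                       x2 = s[principal_labels == "case"])
  })
  names(loc_tests) <- locs
  fdr <- by_fdr(vapply(loc_tests, function(t) t$p, numeric(1)))

  study_rows <- score_table$eye == "study" & score_table$location_id != "overall"
  anova <- rm_anova_group_effect(score_table[study_rows, ])

  overall <- function(eye) {
    rows <- score_table$eye == eye & score_table$location_id == "overall"
    list(scores = score_table$score[rows], labels = score_table$label[rows],
         ids = score_table$subject_id[rows])
  }
  st <- overall("study"); fe <- overall("fellow"); va <- overall("validation")

  # Principal-cohort discrimination on held-out scores (mean over locations)
  loo_overall <- rowMeans(do.call(cbind, loo_scores))
  stats_out <- list(
    location_ttests = loc_tests,
    location_fdr = fdr,
    anova_group = anova,
    roc_principal = roc_auc(loo_overall, principal_labels),
    roc_validation = roc_auc(va$scores, va$labels),
    fellow_correlation = pearson_corr(st$scores, fe$scores)
  )

  result <- list(score_table = score_table, models = models,
                 cv_curves = cv_curves, stats = stats_out, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(score_table, file.path(out_dir, "hs_scores.csv"),
                     row.names = FALSE)
    report <- list(
      seed = config$seed,
      chosen_k = vapply(cv_curves, function(cv) cv$chosen_k, numeric(1)),
      principal_auc = stats_out$roc_principal$auc,
      validation_auc = stats_out$roc_validation$auc,
      fellow_r = stats_out$fellow_correlation$r,
      anova = stats_out$anova_group[c("F", "df1", "df2", "p")],
      location_p = vapply(loc_tests, function(t) t$p, numeric(1)),
      fdr_rejected = stats_out$location_fdr$n_rejected)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
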