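# End-to-end pipeline orchestration: staged artifacts on disk so each stage
# is independently runnable and resumable, plus an in-memory convenience
# wrapper.

#' Pipeline configuration
#'
#' Bundles the cohort simulation settings and the analysis parameters
#' (gray levels, ICC threshold, univariate alpha, CV layout, bootstrap
#' size). Defaults are the values of the analysis this package
#' reimplements: ICC > 0.75, alpha 0.05, 3-fold cross-validation repeated
#' 100 times, 1000 bootstrap resamples.
#'
#' @param cohort A [cohort_config()].
#' @param G Gray levels for texture discretization.
#' @param icc_threshold Reliability retention threshold.
#' @param alpha Univariate retention threshold.
#' @param folds,repeats LASSO cross-validation layout.
#' @param B Bootstrap resamples.
#' @param seed Analysis seed (cross-validation and bootstrap; the cohort
#'   has its own seed inside `cohort`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), G = 32L,
                            icc_threshold = 0.75, alpha = 0.05,
                            folds = 3L, repeats = 100L, B = 1000L,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            G >= 2, icc_threshold >= 0, icc_threshold <= 1,
            alpha > 0, alpha < 1, folds >= 2, repeats >= 1, B >= 1)
  structure(list(cohort = cohort, G = as.integer(G),
                 icc_threshold = icc_threshold, alpha = alpha,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 B = as.integer(B), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis in memory
#'
#' Simulates a cohort, extracts both readers' features, applies the
#' three-step selection ([fit_radscore()]), scores and dichotomizes the
#' cohort, and compares the clinical and clinical + Rad-score models. Every
#' number is reproducible from the two seeds in `config`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, all stage artifacts
#'   (CSV/JSON and a parameter log) are also written to disk.
#' @return List with `cohort` (scored), `features_reader1`,
#'   `features_reader2`, `reliability`, `fit` (a `radscore_fit`),
#'   `comparison` (a `pdl1_model_comparison`) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- generate_cohort(config$cohort)
  cohort <- sim$cohort
  f1 <- extract_cohort_features(sim$volumes, cohort$subject_id, G = config$G)
  vols2 <- mapply(function(v, m2) volume_with_mask(v$intensities, m2,
                                                   v$spacing_mm),
                  sim$volumes, sim$masks_reader2, SIMPLIFY = FALSE)
  f2 <- extract_cohort_features(vols2, cohort$subject_id, G = config$G)
  fit <- fit_radscore(f1, cohort$label, features_reader2 = f2,
                      icc_threshold = config$icc_threshold,
                      alpha = config$alpha, folds = config$folds,
                      repeats = config$repeats, seed = config$seed)
  cohort$rad_score <- fit$scores
  cohort$rad_score_positive <- dichotomize(cohort$rad_score,
                                           fit$signature$cutoff, "gt")
  comparison <- compare_models(cohort, rad_cutoff = fit$signature$cutoff,
                               B = config$B, seed = config$seed)
  out <- list(cohort = cohort, features_reader1 = f1, features_reader2 = f2,
              reliability = fit$step1, fit = fit, comparison = comparison,
              config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_cohort_table(res$cohort, p("cohort_scored.csv"))
  write_feature_table(res$features_reader1, p("features_reader1.csv"))
  write_feature_table(res$features_reader2, p("features_reader2.csv"))
  if (!is.null(res$reliability$icc_table))
    utils::write.csv(res$reliability$icc_table, p("icc_table.csv"),
                     row.names = FALSE)
  utils::write.csv(res$fit$step2$p_table, p("univariate_p_values.csv"),
                   row.names = FALSE)
  sel <- res$fit$selection
  jsonlite::write_json(
    list(step1_retained = res$fit$step1$retained,
         step2_retained = res$fit$step2$retained,
         lambda_grid = sel$lambda_grid,
         mean_auc_per_lambda = sel$mean_auc_per_lambda,
         chosen_lambda = sel$chosen_lambda,
         nonzero_features = as.list(sel$nonzero_features),
         intercept = sel$intercept,
         folds = sel$folds, repeats = sel$repeats, seed = sel$seed),
    p("selection_report.json"), auto_unbox = TRUE, digits = NA)
  write_signature_json(res$fit$signature, p("signature.json"))
  utils::write.csv(comparison_table(res$comparison),
                   p("model_comparison.csv"), row.names = FALSE)
  log <- c(sprintf("radpdl1 %s", as.character(utils::packageVersion("radpdl1"))),
           sprintf("cohort seed: %d", res$config$cohort$seed),
           sprintf("analysis seed: %d", res$config$seed),
           sprintf("n_subjects: %d", res$config$cohort$n_subjects),
           sprintf("prevalence: %.6f", res$config$cohort$prevalence),
           sprintf("effect_homogeneity: %g", res$config$cohort$effect_homogeneity),
           sprintf("G: %d  icc_threshold: %g  alpha: %g", res$config$G,
                   res$config$icc_threshold, res$config$alpha),
           sprintf("folds: %d  repeats: %d  B: %d", res$config$folds,
                   res$config$repeats, res$config$B))
  writeLines(log, p("pipeline_log.txt"))
  invisible(out_dir)
}

#' Score a feature table with a signature
#'
#' Convenience for applying a (e.g. the published) signature to an
#' extracted feature table: adds `rad_score` and, when the signature has a
#' cutoff, `rad_score_positive` columns.
#'
#' @param features Feature table (data frame) containing the signature's
#'   feature columns.
#' @param sig A [rad_signature()]; default the published one.
#' @return `features` with the score column(s) appended.
#' @export
score_feature_table <- function(features, sig = published_signature()) {
  features$rad_score <- rad_score(sig, drop_id_columns(features))
  if (!is.null(sig$cutoff))
    features$rad_score_positive <- dichotomize(features$rad_score,
                                               sig$cutoff, "gt")
  features
}
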