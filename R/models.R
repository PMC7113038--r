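# Logistic prediction models, paired c-statistic comparison (DeLong) and
# bootstrap optimism-corrected internal validation.

#' Fit a logistic prediction model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a table of
#' numeric covariates, reporting Wald odds ratios with 95% confidence
#' intervals, the per-subject linear predictor, and the c-statistic
#' (concordance AUC of the linear predictor) with a DeLong-variance 95% CI.
#' Perfect separation is flagged and the affected confidence intervals
#' suppressed.
#'
#' @param design Data frame of numeric covariates (no constant column).
#' @param labels Binary outcome.
#' @return Object of class `pdl1_logit`: list with `glm`, `or_table`,
#'   `linear_predictor`, `c_statistic`, `c_ci`, `separation`.
#' @export
fit_logistic <- function(design, labels) {
  labels <- check_binary_labels(labels)
  design <- as.data.frame(design)
  if (!nrow(design) || nrow(design) != length(labels))
    stop("design/labels size mismatch")
  if (nrow(design) <= ncol(design) + 1L)
    stop("need more subjects than model terms")
  if (any(vapply(design, function(v) stats::sd(as.numeric(v)) == 0,
                 logical(1))))
    stop("constant covariate in design")
  dat <- cbind(design, .y = labels)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    sep <- TRUE
  cf <- summary(fit)$coefficients
  terms <- rownames(cf)[-1]
  or <- exp(cf[-1, 1])
  se <- cf[-1, 2]
  or_table <- data.frame(
    term = terms, or = unname(or),
    ci_low = if (sep) NA_real_ else unname(exp(cf[-1, 1] - 1.96 * se)),
    ci_high = if (sep) NA_real_ else unname(exp(cf[-1, 1] + 1.96 * se)),
    p_value = unname(cf[-1, 4]),
    stringsAsFactors = FALSE)
  lp <- unname(fit$linear.predictors)
  cstat <- if (stats::sd(lp) == 0) 0.5 else auc_concordance(lp, labels)
  cci <- if (stats::sd(lp) == 0) c(0.5, 0.5) else {
    v <- delong_auc_variance(lp, labels)
    pmin(pmax(cstat + c(-1.96, 1.96) * sqrt(v), 0), 1)
  }
  structure(list(glm = fit, or_table = or_table, linear_predictor = lp,
                 c_statistic = cstat, c_ci = cci, separation = sep,
                 labels = labels),
            class = "pdl1_logit")
}

#' @export
print.pdl1_logit <- function(x, ...) {
  cat("Logistic model for PD-L1 positivity\n")
  tab <- x$or_table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-22s OR %.4f (%.4f-%.4f)  P = %.4f\n", tab$term[i],
                tab$or[i], tab$ci_low[i], tab$ci_high[i], tab$p_value[i]))
  cat(sprintf("  c-statistic %.3f (95%% CI %.3f-%.3f)%s\n", x$c_statistic,
              x$c_ci[1], x$c_ci[2],
              if (x$separation) "  [perfect separation flagged]" else ""))
  invisible(x)
}

# DeLong placement values: for each positive subject the fraction of
# negatives it outscores (ties 1/2), and vice versa.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_auc_variance <- function(scores, labels) {
  p <- delong_placements(scores, labels)
  stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors over the same
#' subjects, using the structural-components (DeLong) variance of the AUC
#' difference. Returns a two-sided p-value; a degenerate (zero) variance -
#' e.g. identical or rank-identical scores - yields delta 0 handling with
#' p = 1 by convention.
#'
#' @param scores1,scores2 Score vectors over the same subjects.
#' @param labels Binary labels (both classes present).
#' @return List with `auc1`, `auc2`, `delta` (auc2 - auc1), `z`, `p`.
#' @export
delong_compare <- function(scores1, scores2, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores1) == length(labels),
            length(scores2) == length(labels))
  p1 <- delong_placements(scores1, labels)
  p2 <- delong_placements(scores2, labels)
  n1 <- length(p1$v10); n0 <- length(p1$v01)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- p2$auc - p1$auc
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc1 = p1$auc, auc2 = p2$auc, delta = delta, z = z, p = p)
}

#' Bootstrap optimism-corrected c-index
#'
#' Standard resample-refit internal validation: for each stratified
#' bootstrap resample the model is refit, its apparent AUC on the resample
#' minus the AUC of the resampled model applied to the original data is the
#' optimism; the corrected c-index is the apparent c-index minus the mean
#' optimism over `B` resamples. Resampling is stratified by outcome so no
#' resample is single-class (plain resampling available via
#' `stratified = FALSE`, in which case single-class draws are redrawn).
#'
#' @param design Data frame of numeric covariates.
#' @param labels Binary outcome.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param stratified Stratify resampling by outcome (default `TRUE`).
#' @return List with `apparent_c`, `optimism`, `corrected_c`, `B`,
#'   and `boot_apparent_c` (the per-resample apparent c-indices).
#' @export
bootstrap_optimism <- function(design, labels, B = 1000L, seed = 1L,
                               stratified = TRUE) {
  res <- boot_validate(list(as.data.frame(design)), labels, B = B,
                       seed = seed, stratified = stratified)
  list(apparent_c = res$apparent[1], optimism = res$optimism[1],
       corrected_c = res$corrected[1], B = B,
       boot_apparent_c = res$boot_apparent[, 1])
}

# Shared-resample bootstrap validation of several nested models.
boot_validate <- function(designs, labels, B = 1000L, seed = 1L,
                          stratified = TRUE) {
  labels <- check_binary_labels(labels)
  Xs <- lapply(designs, function(d) cbind(1, as.matrix(d)))
  M <- length(Xs)
  apparent <- numeric(M)
  lp_full <- vector("list", M)
  for (m in seq_len(M)) {
    f <- suppressWarnings(stats::glm.fit(Xs[[m]], labels,
                                         family = stats::binomial()))
    lp_full[[m]] <- drop(Xs[[m]] %*% f$coefficients)
    apparent[m] <- auc_concordance(lp_full[[m]], labels)
  }
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  opt <- matrix(0, B, M)
  boot_app <- matrix(0, B, M)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        if (stratified) {
          take <- c(sample(idx1, length(idx1), replace = TRUE),
                    sample(idx0, length(idx0), replace = TRUE))
        } else {
          take <- sample.int(length(labels), replace = TRUE)
        }
        if (length(unique(labels[take])) == 2L) break
      }
      yb <- labels[take]
      for (m in seq_len(M)) {
        Xb <- Xs[[m]][take, , drop = FALSE]
        fb <- suppressWarnings(stats::glm.fit(Xb, yb,
                                              family = stats::binomial()))
        lp_b <- drop(Xb %*% fb$coefficients)
        lp_o <- drop(Xs[[m]] %*% fb$coefficients)
        boot_app[b, m] <- auc_concordance(lp_b, yb)
        opt[b, m] <- boot_app[b, m] - auc_concordance(lp_o, labels)
      }
    }
  })
  list(apparent = apparent, optimism = colMeans(opt),
       corrected = apparent - colMeans(opt), boot_apparent = boot_app)
}

#' Compare the clinical and clinical + Rad-score logistic models
#'
#' Builds the two nested prediction models of the analysis: Model 1 on the
#' dichotomized clinical variables (age at or below the cutoff, female sex,
#' current-or-ex smoker, EGFR mutation; reference levels are older age,
#' male, never-smoker and wild-type) and Model 2 adding the dichotomized
#' Rad-score (score strictly above its cutoff). Reports Wald odds-ratio
#' tables, c-statistics with DeLong CIs, the paired DeLong test between the
#' two models, and shared-resample bootstrap optimism-corrected c-indices
#' with a percentile CI for the c-statistic difference.
#'
#' @param cohort A cohort data frame with columns `age`, `sex`, `smoking`,
#'   `egfr`, `label` and `rad_score` (continuous).
#' @param rad_cutoff Rad-score cutoff; default the Youden cutoff computed
#'   on this cohort.
#' @param age_cutoff Age cutoff in years; default the Youden cutoff of age
#'   against the label.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param stratified Stratified bootstrap (default `TRUE`).
#' @return Object of class `pdl1_model_comparison`: list with `model1`,
#'   `model2` ([fit_logistic()] objects), `delong`, `bootstrap` (corrected
#'   c-indices, optimism, `delta_ci`), `age_cutoff`, `rad_cutoff`,
#'   `univariate` (per-variable single-covariate odds ratios).
#' @export
compare_models <- function(cohort, rad_cutoff = NULL, age_cutoff = NULL,
                           B = 1000L, seed = 1L, stratified = TRUE) {
  need <- c("age", "sex", "smoking", "egfr", "label", "rad_score")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  labels <- check_binary_labels(cohort$label)
  if (is.null(age_cutoff))
    age_cutoff <- youden_cutoff(cohort$age, labels)$cutoff
  if (is.null(rad_cutoff))
    rad_cutoff <- youden_cutoff(cohort$rad_score, labels)$cutoff
  d1 <- data.frame(
    age_le_cutoff = dichotomize(cohort$age, age_cutoff, "le"),
    female = as.integer(cohort$sex == "female"),
    ever_smoker = as.integer(cohort$smoking %in% c("current", "past")),
    egfr_mutation = as.integer(cohort$egfr == 1))
  d2 <- cbind(d1, radscore_positive = dichotomize(cohort$rad_score,
                                                  rad_cutoff, "gt"))
  m1 <- fit_logistic(d1, labels)
  m2 <- fit_logistic(d2, labels)
  dl <- delong_compare(m1$linear_predictor, m2$linear_predictor, labels)
  bv <- boot_validate(list(d1, d2), labels, B = B, seed = seed,
                      stratified = stratified)
  delta_boot <- bv$boot_apparent[, 2] - bv$boot_apparent[, 1]
  uni <- lapply(names(d2), function(nm) {
    f <- fit_logistic(d2[, nm, drop = FALSE], labels)
    cbind(f$or_table, c_statistic = f$c_statistic)
  })
  uni <- do.call(rbind, uni)
  structure(list(model1 = m1, model2 = m2, delong = dl,
                 bootstrap = list(
                   corrected_c = bv$corrected, optimism = bv$optimism,
                   apparent_c = bv$apparent,
                   delta_ci = stats::quantile(delta_boot, c(0.025, 0.975),
                                              names = FALSE),
                   B = B),
                 age_cutoff = age_cutoff, rad_cutoff = rad_cutoff,
                 univariate = uni, labels = labels),
            class = "pdl1_model_comparison")
}

#' @export
print.pdl1_model_comparison <- function(x, ...) {
  cat("PD-L1 prediction models\n")
  cat(sprintf("  age cutoff %.1f years; Rad-score cutoff %.4f\n",
              x$age_cutoff, x$rad_cutoff))
  cat("\nModel 1 (clinical variables)\n")
  print(x$model1)
  cat("\nModel 2 (clinical variables + Rad-score)\n")
  print(x$model2)
  cat(sprintf("\nDeLong comparison: delta c = %.4f, P = %.4f\n",
              x$delong$delta, x$delong$p))
  cat(sprintf("Bootstrap (B = %d): corrected c %.3f vs %.3f; delta c 95%% CI %.3f-%.3f\n",
              x$bootstrap$B, x$bootstrap$corrected_c[1],
              x$bootstrap$corrected_c[2], x$bootstrap$delta_ci[1],
              x$bootstrap$delta_ci[2]))
  invisible(x)
}

#' Tabulate a model comparison in the shape of the published tables
#'
#' @param x A [compare_models()] result.
#' @return A data frame with one row per term and model, odds ratios,
#'   95% CIs, p-values, and summary rows for the (bootstrapped)
#'   c-statistics.
#' @export
comparison_table <- function(x) {
  stopifnot(inherits(x, "pdl1_model_comparison"))
  row <- function(model, tab) {
    data.frame(model = model, term = tab$term, or = tab$or,
               ci_low = tab$ci_low, ci_high = tab$ci_high,
               p_value = tab$p_value, stringsAsFactors = FALSE)
  }
  out <- rbind(row("model1", x$model1$or_table),
               row("model2", x$model2$or_table))
  extra <- data.frame(
    model = c("model1", "model2", "comparison", "model1", "model2"),
    term = c("c_statistic", "c_statistic", "delong_p",
             "bootstrap_corrected_c", "bootstrap_corrected_c"),
    or = c(x$model1$c_statistic, x$model2$c_statistic, x$delong$p,
           x$bootstrap$corrected_c),
    ci_low = c(x$model1$c_ci[1], x$model2$c_ci[1], NA,
               NA, x$bootstrap$delta_ci[1]),
    ci_high = c(x$model1$c_ci[2], x$model2$c_ci[2], NA,
                NA, x$bootstrap$delta_ci[2]),
    p_value = NA, stringsAsFactors = FALSE)
  rbind(out, extra)
}

#' Group comparison test for a clinical 2 x k table
#'
#' Chi-square test with Yates continuity correction for 2 x 2 tables,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5 (the usual practice for sparse clinical tables).
#'
#' @param x,y Categorical vectors (e.g. a covariate and the PD-L1 label).
#' @return List with `p_value` and `method`.
#' @export
categorical_group_test <- function(x, y) {
  tab <- table(x, y)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 5)) {
    list(p_value = stats::fisher.test(tab)$p.value, method = "fisher")
  } else {
    list(p_value = stats::chisq.test(tab, correct = nrow(tab) == 2 &&
                                       ncol(tab) == 2)$p.value,
         method = "chisq")
  }
}
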