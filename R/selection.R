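# Three-step feature selection: ICC reliability filter, univariate t-test
# screen, and repeated-cross-validation LASSO, ending in a Rad-score
# signature. `fit_radscore()` is the modelling front-end.

#' Univariate t-test screen
#'
#' Per-feature two-sample t-test (pooled-variance Student's t by default,
#' matching classic statistical-package defaults; Welch available) of
#' PD-L1-positive versus negative subjects. Features with `p < alpha` are
#' retained. A feature with zero variance in both classes carries no
#' information: its p-value is defined as 1 and flagged.
#'
#' @param features Data frame or matrix of feature columns (id columns
#'   `subject_id`/`label` are ignored).
#' @param labels Binary labels, at least 2 subjects per class.
#' @param alpha Retention threshold on the p-value.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `retained` (feature names) and `p_table` (data frame:
#'   feature, p_value, degenerate).
#' @export
univariate_screen <- function(features, labels, alpha = 0.05,
                              var_equal = TRUE) {
  labels <- check_binary_labels(labels)
  x <- drop_id_columns(features)
  if (nrow(x) != length(labels)) stop("row/label length mismatch")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  res <- vapply(colnames(x), function(nm) {
    v <- x[[nm]]
    v1 <- v[labels == 1L]; v0 <- v[labels == 0L]
    if (stats::sd(v1) == 0 && stats::sd(v0) == 0) return(c(1, 1))
    p <- tryCatch(stats::t.test(v1, v0, var.equal = var_equal)$p.value,
                  error = function(e) 1)
    c(p, 0)
  }, numeric(2))
  p_table <- data.frame(feature = colnames(x), p_value = res[1, ],
                        degenerate = res[2, ] == 1, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(retained = p_table$feature[p_table$p_value < alpha],
       p_table = p_table)
}

#' LASSO selection by repeated cross-validated AUC
#'
#' Fits L1-penalized logistic regressions over a log-spaced lambda grid
#' (from the data-derived maximal lambda down by a factor 1e-4). Stratified
#' k-fold cross-validation is repeated `repeats` times; for every lambda the
#' validation AUC is computed in each fold and averaged over all
#' `folds * repeats` validation folds. The chosen lambda maximizes this mean
#' AUC (ties broken toward the larger lambda, i.e. the sparser model); the
#' final model is refit on all data at the chosen lambda. Features are
#' z-scored internally for penalization; reported coefficients are on the
#' raw feature scale. Deterministic given `seed`.
#'
#' @param features Data frame or matrix of candidate features (id columns
#'   ignored).
#' @param labels Binary labels with at least `folds` subjects per class.
#' @param folds Number of CV folds (default 3).
#' @param repeats Number of CV repetitions (default 100).
#' @param seed Integer seed for fold assignment.
#' @param nlambda Grid size.
#' @param lambda_min_ratio Ratio of smallest to largest grid lambda.
#' @param lambda Optional user-supplied decreasing lambda grid overriding
#'   the data-derived one.
#' @return An object of class `selection_report`: list with `lambda_grid`,
#'   `mean_auc_per_lambda`, `chosen_lambda`, `chosen_mean_auc`,
#'   `nonzero_features` (named coefficients, raw scale), `intercept`,
#'   `folds`, `repeats`, `seed`, `feature_names`.
#' @export
lasso_cv_select <- function(features, labels, folds = 3L, repeats = 100L,
                            seed = 1L, nlambda = 100L,
                            lambda_min_ratio = 1e-4, lambda = NULL) {
  labels <- check_binary_labels(labels)
  x <- as.matrix(drop_id_columns(features))
  storage.mode(x) <- "double"
  if (nrow(x) != length(labels)) stop("row/label length mismatch")
  if (min(table(labels)) < folds)
    stop("need at least 'folds' subjects per class")
  if (ncol(x) < 2L)
    stop("LASSO selection needs at least 2 candidate features")
  # lambda grid from the maximal gradient of the standardized design
  if (is.null(lambda)) {
    xs <- scale(x)
    xs[, attr(xs, "scaled:scale") == 0] <- 0
    lmax <- max(abs(crossprod(xs, labels - mean(labels)))) / nrow(x)
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
  } else {
    grid <- sort(as.numeric(lambda), decreasing = TRUE)
    nlambda <- length(grid)
  }
  auc_sum <- numeric(nlambda)
  auc_n <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(labels, folds)
      for (k in seq_len(folds)) {
        tr <- fold != k
        if (length(unique(labels[!tr])) < 2L) next
        fit <- glmnet::glmnet(x[tr, , drop = FALSE], labels[tr],
                              family = "binomial", lambda = grid,
                              standardize = TRUE)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE], s = grid)
        auc_sum <- auc_sum + apply(pred, 2, auc_concordance,
                                   labels = labels[!tr])
        auc_n <- auc_n + 1L
      }
    }
  })
  mean_auc <- unname(auc_sum / auc_n)
  best <- which(mean_auc == max(mean_auc))[1L]   # grid descending: sparser
  chosen <- grid[best]
  final <- glmnet::glmnet(x, labels, family = "binomial", lambda = grid,
                          standardize = TRUE)
  cf <- drop(as.matrix(stats::coef(final, s = chosen)))
  nz <- cf[-1][cf[-1] != 0]
  if (!length(nz))
    warning("no feature has a nonzero coefficient at the chosen lambda; ",
            "intercept-only signature")
  structure(list(lambda_grid = grid, mean_auc_per_lambda = mean_auc,
                 chosen_lambda = chosen, chosen_mean_auc = mean_auc[best],
                 nonzero_features = nz, intercept = unname(cf[1]),
                 folds = folds, repeats = repeats, seed = seed,
                 feature_names = colnames(x)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat(sprintf("  %d candidate features; lambda grid of %d values\n",
              length(x$feature_names), length(x$lambda_grid)))
  cat(sprintf("  %d-fold CV x %d repeats: best mean AUC %.3f at lambda %.5g\n",
              x$folds, x$repeats, x$chosen_mean_auc, x$chosen_lambda))
  cat(sprintf("  %d nonzero feature(s): %s\n", length(x$nonzero_features),
              paste(names(x$nonzero_features), collapse = ", ")))
  invisible(x)
}

#' Build a Rad-score signature from a selection report
#'
#' @param report A [lasso_cv_select()] result.
#' @param cutoff Optional classification cutoff to attach.
#' @param name Optional signature name.
#' @return A [rad_signature()] with the report's intercept and raw-scale
#'   nonzero coefficients.
#' @export
build_signature <- function(report, cutoff = NULL, name = NULL) {
  stopifnot(inherits(report, "selection_report"))
  rad_signature(report$intercept, report$nonzero_features, cutoff = cutoff,
                name = name)
}

#' Fit a Rad-score model by three-step feature selection
#'
#' The modelling front-end of the package. Starting from the full radiomic
#' feature table it applies, in order: (1) the interobserver reliability
#' filter (features with two-reader ICC > `icc_threshold`; skipped when no
#' second-reader table is supplied), (2) the univariate t-test screen at
#' `alpha`, and (3) LASSO logistic regression with the lambda maximizing the
#' repeated cross-validated AUC. The resulting signature (raw-scale
#' coefficients) is evaluated on the training cohort and the ROC-optimal
#' Youden cutoff is attached.
#'
#' @param features Data frame with the 58 radiomic feature columns
#'   (id columns are ignored for fitting).
#' @param labels Binary PD-L1 labels.
#' @param features_reader2 Optional second-reader feature table for the
#'   reliability step.
#' @param icc_threshold ICC retention threshold (default 0.75).
#' @param alpha Univariate retention threshold (default 0.05).
#' @param folds,repeats Cross-validation layout of the LASSO step
#'   (default 3 x 100).
#' @param seed Integer seed (fold assignment).
#' @return An object of class `radscore_fit` with `print()`, `summary()`,
#'   `coef()` and `predict()` methods. Elements include `signature`
#'   ([rad_signature()] with Youden cutoff), `selection` (the
#'   [lasso_cv_select()] report), `step1`/`step2` (per-step retained
#'   features and diagnostics), `scores` (training Rad-scores), `roc`
#'   (cutoff, sensitivity, specificity, AUC) and `labels`.
#' @export
fit_radscore <- function(features, labels, features_reader2 = NULL,
                         icc_threshold = 0.75, alpha = 0.05,
                         folds = 3L, repeats = 100L, seed = 1L) {
  labels <- check_binary_labels(labels)
  x <- drop_id_columns(features)
  if (!is.null(features_reader2)) {
    step1 <- reliability_filter(features, features_reader2,
                                threshold = icc_threshold)
  } else {
    step1 <- list(retained = colnames(x), icc_table = NULL)
  }
  if (!length(step1$retained))
    stop("no feature passed the reliability filter")
  step2 <- univariate_screen(x[, step1$retained, drop = FALSE], labels,
                             alpha = alpha)
  if (length(step2$retained) < 2L)
    stop("fewer than 2 features passed the univariate screen; ",
         "no LASSO model can be selected")
  selection <- lasso_cv_select(x[, step2$retained, drop = FALSE], labels,
                               folds = folds, repeats = repeats, seed = seed)
  sig <- build_signature(selection, name = "radscore_fit")
  scores <- rad_score(sig, x)
  roc <- if (length(unique(scores)) >= 2L) youden_cutoff(scores, labels)
         else NULL
  if (!is.null(roc)) sig$cutoff <- roc$cutoff
  structure(list(signature = sig, selection = selection,
                 step1 = step1, step2 = step2,
                 scores = scores, roc = roc, labels = labels,
                 icc_threshold = icc_threshold, alpha = alpha,
                 n = length(labels), seed = seed),
            class = "radscore_fit")
}

#' @export
print.radscore_fit <- function(x, ...) {
  cat("Rad-score model (three-step selection + cross-validated LASSO)\n")
  cat(sprintf("  n = %d (%d positive), %d -> %d -> %d features\n",
              x$n, sum(x$labels),
              length(x$step1$retained %||% character(0)),
              length(x$step2$retained),
              length(x$selection$nonzero_features)))
  print(x$signature)
  if (!is.null(x$roc))
    cat(sprintf("  training AUC %.3f; Youden cutoff %.4f (sens %.3f, spec %.3f)\n",
                x$roc$auc, x$roc$cutoff, x$roc$sensitivity, x$roc$specificity))
  invisible(x)
}

#' @export
summary.radscore_fit <- function(object, ...) {
  s1 <- object$step1$icc_table
  cat("Three-step radiomic feature selection\n")
  cat(sprintf("Step 1 (reliability, ICC > %.2f): %s features retained\n",
              object$icc_threshold,
              if (is.null(s1)) "skipped; all"
              else as.character(length(object$step1$retained))))
  cat(sprintf("Step 2 (t-test, p < %.2f): %d features retained\n",
              object$alpha, length(object$step2$retained)))
  print(object$selection)
  if (!is.null(object$roc)) {
    cat(sprintf("Rad-score: mean %.3f (positives) vs %.3f (negatives)\n",
                mean(object$scores[object$labels == 1L]),
                mean(object$scores[object$labels == 0L])))
    cat(sprintf("Training ROC: AUC %.3f, Youden cutoff %.4f, sens %.1f%%, spec %.1f%%\n",
                object$roc$auc, object$roc$cutoff,
                100 * object$roc$sensitivity, 100 * object$roc$specificity))
  }
  invisible(object)
}

#' @export
coef.radscore_fit <- function(object, ...) coef(object$signature)

#' @export
predict.radscore_fit <- function(object, newdata,
                                 type = c("score", "class"), ...) {
  type <- match.arg(type)
  predict(object$signature, drop_id_columns(newdata), type = type)
}
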