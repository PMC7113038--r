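# Univariate screen, cross-validated LASSO selection, and the
# fit_radscore front-end.

make_noise_features <- function(n, p, seed, names_from_catalogue = TRUE) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  colnames(x) <- if (names_from_catalogue) radiomic_feature_names()[seq_len(p)]
                 else paste0("f", seq_len(p))
  x
}

test_that("univariate screen retains powered effects and drops constants", {
  set.seed(1)
  n <- 150
  y <- rep(0:1, length.out = n)
  x <- make_noise_features(n, 10, seed = 2, names_from_catalogue = FALSE)
  x$f1 <- rnorm(n, mean = 2 * y)        # 2-SD group separation: power ~ 1
  x$f2 <- rep(3.14, n)                  # constant: defined p = 1
  sc <- univariate_screen(x, y)
  expect_true("f1" %in% sc$retained)
  expect_false("f2" %in% sc$retained)
  expect_equal(sc$p_table$p_value[sc$p_table$feature == "f2"], 1)
  expect_true(sc$p_table$degenerate[sc$p_table$feature == "f2"])
})

test_that("under the null the screen retains about alpha * p features", {
  n <- 100
  counts <- vapply(1:12, function(s) {
    x <- make_noise_features(n, 58, seed = 100 + s)
    y <- rep(0:1, length.out = n)
    length(univariate_screen(x, y)$retained)
  }, numeric(1))
  # expectation 58 * 0.05 = 2.9
  expect_gt(mean(counts), 1.2)
  expect_lt(mean(counts), 5.2)
})

test_that("LASSO CV selection is deterministic and reports a coherent grid", {
  set.seed(3)
  n <- 90
  y <- rep(0:1, length.out = n)
  x <- make_noise_features(n, 8, seed = 4)
  x[[1]] <- x[[1]] + 1.2 * y
  r1 <- lasso_cv_select(x, y, repeats = 5, seed = 11)
  r2 <- lasso_cv_select(x, y, repeats = 5, seed = 11)
  expect_identical(r1, r2)
  r3 <- lasso_cv_select(x, y, repeats = 1, seed = 11)
  expect_identical(r1$lambda_grid, r3$lambda_grid)
  expect_false(identical(r1$mean_auc_per_lambda, r3$mean_auc_per_lambda))
  expect_length(r1$lambda_grid, 100)
  expect_true(all(diff(r1$lambda_grid) < 0))
  expect_equal(r1$chosen_mean_auc, max(r1$mean_auc_per_lambda))
  expect_equal(r1$chosen_lambda,
               r1$lambda_grid[which.max(r1$mean_auc_per_lambda)])
})

test_that("raw-scale signature reproduces the penalized fit's link exactly", {
  set.seed(5)
  n <- 120
  y <- rep(0:1, length.out = n)
  x <- make_noise_features(n, 6, seed = 6)
  x[[2]] <- x[[2]] + 1.5 * y
  r <- lasso_cv_select(x, y, repeats = 3, seed = 2)
  sig <- build_signature(r)
  scores <- rad_score(sig, x)
  fit <- glmnet::glmnet(as.matrix(x), y, family = "binomial",
                        lambda = r$lambda_grid, standardize = TRUE)
  link <- drop(predict(fit, as.matrix(x), s = r$chosen_lambda))
  expect_equal(scores, unname(link), tolerance = 1e-10)
})

test_that("a strongly planted feature is recovered across seeds", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 150
    y <- rep(0:1, length.out = n)
    x <- make_noise_features(n, 21, seed = 300 + s)
    x[[7]] <- rnorm(n, mean = 2 * y)
    r <- lasso_cv_select(x, y, repeats = 5, seed = s)
    if (colnames(x)[7] %in% names(r$nonzero_features)) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("pure-noise features give near-chance cross-validated AUC", {
  set.seed(7)
  n <- 150
  y <- rep(0:1, length.out = n)
  x <- make_noise_features(n, 20, seed = 8)
  r <- lasso_cv_select(x, y, repeats = 10, seed = 9)
  expect_lte(r$chosen_mean_auc, 0.6)
})

test_that("fit_radscore runs the three steps as a monotone pipeline", {
  set.seed(10)
  n <- 120
  y <- rep(0:1, length.out = n)
  x <- make_noise_features(n, 58, seed = 11)
  x$Texture_GLRLM_RV <- rnorm(n, 1.6 * y)
  x$Texture_GLCM_ASM <- rnorm(n, 1.2 * y)
  x2 <- x + matrix(rnorm(n * 58, 0, 0.05), n, 58)  # high-agreement reader 2
  fit <- fit_radscore(x, y, features_reader2 = x2, repeats = 5, seed = 12)
  expect_s3_class(fit, "radscore_fit")
  expect_true(all(fit$step2$retained %in% fit$step1$retained))
  expect_true(all(names(fit$selection$nonzero_features) %in%
                  fit$step2$retained))
  expect_true("Texture_GLRLM_RV" %in% names(fit$selection$nonzero_features))
  # the attached cutoff is the Youden optimum of the training scores
  yj <- youden_cutoff(fit$scores, y)
  expect_equal(fit$signature$cutoff, yj$cutoff)
  # predict() reproduces the training scores
  expect_equal(predict(fit, x), fit$scores)
  expect_equal(unname(coef(fit)[1]), fit$selection$intercept)
  expect_output(print(fit), "Rad-score")
})

test_that("an all-noise problem yields an intercept-only signature warning", {
  set.seed(13)
  n <- 40
  y <- rep(0:1, length.out = n)
  x <- make_noise_features(n, 5, seed = 14)
  # a grid of overwhelming penalties shrinks everything to zero
  expect_warning(r <- lasso_cv_select(x, y, repeats = 2, seed = 1,
                                      lambda = c(50, 20, 10)),
                 "intercept-only")
  sig <- build_signature(r)
  expect_length(sig$coefficients, 0)
  expect_equal(rad_score(sig, x), rep(sig$intercept, n))
})
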