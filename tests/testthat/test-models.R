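# Logistic model fits, DeLong comparison, bootstrap optimism, model
# comparison report.

test_that("logistic fit reproduces the 2x2 closed form", {
  # cells: (x=1,y=1)=20, (x=1,y=0)=10, (x=0,y=1)=10, (x=0,y=0)=20
  x <- c(rep(1, 30), rep(0, 30))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  m <- fit_logistic(data.frame(exposure = x), y)
  expect_equal(m$or_table$or, 4.0, tolerance = 1e-6)
  se <- log(m$or_table$ci_high / m$or_table$or) / 1.96
  expect_equal(se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20), tolerance = 1e-4)
  expect_false(m$separation)
})

test_that("null covariates give OR near 1 and intercept-only gives c = 0.5", {
  set.seed(1)
  n <- 4000
  y <- rbinom(n, 1, 0.4)
  m <- fit_logistic(data.frame(z = rnorm(n)), y)
  expect_lt(abs(m$or_table$or - 1), 0.1)
  m0 <- fit_logistic(data.frame(row.names = seq_len(50)),
                     rep(0:1, length.out = 50))
  expect_equal(m0$c_statistic, 0.5)
  expect_error(fit_logistic(data.frame(k = rep(1, 20)),
                            rep(0:1, length.out = 20)), "constant covariate")
})

test_that("perfect separation is flagged and CIs suppressed", {
  y <- rep(0:1, each = 15)
  m <- fit_logistic(data.frame(s = y + rnorm(30, 0, 1e-4)), y)
  expect_true(m$separation)
  expect_true(all(is.na(m$or_table$ci_low)))
})

test_that("DeLong comparison honors its degenerate and rank contracts", {
  set.seed(2)
  y <- rbinom(40, 1, 0.5); y[1:2] <- 0:1
  s1 <- rnorm(40)
  d <- delong_compare(s1, s1, y)
  expect_equal(d$delta, 0)
  expect_equal(d$p, 1)
  # monotone transform: identical ranks, delta exactly 0
  d2 <- delong_compare(s1, exp(2 * s1) + 5, y)
  expect_equal(d2$delta, 0)
  expect_equal(d2$p, 1)
  # antisymmetry of delta
  s2 <- rnorm(40)
  expect_equal(delong_compare(s1, s2, y)$delta,
               -delong_compare(s2, s1, y)$delta)
})

test_that("DeLong test agrees with pROC on random paired scores", {
  skip_if_not_installed("pROC")
  for (s in 1:5) {
    set.seed(s)
    n <- 60
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    base <- rnorm(n) + y
    s1 <- base + rnorm(n, 0, 0.8)
    s2 <- base + rnorm(n, 0, 1.2)
    got <- delong_compare(s1, s2, y)
    r1 <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
    r2 <- pROC::roc(y, s2, quiet = TRUE, direction = "<")
    ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-8)
    expect_equal(got$auc1, as.numeric(r1$auc), tolerance = 1e-12)
  }
})

test_that("DeLong p is close to a sign-swap permutation oracle at n = 30", {
  set.seed(6)
  n <- 30
  y <- c(rep(1, 12), rep(0, 18))
  base <- rnorm(n) + 0.8 * y
  s1 <- base + rnorm(n, 0, 1)
  s2 <- base + rnorm(n, 0, 1) + 0.5 * y
  got <- delong_compare(s1, s2, y)
  p_perm <- oracle_delong_permutation(s1, s2, y, B = 2000, seed = 1)
  expect_lt(abs(got$p - p_perm), 0.1)
})

test_that("bootstrap optimism correction behaves under pure noise", {
  set.seed(7)
  n <- 150
  y <- rep(0:1, length.out = n)
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  b <- bootstrap_optimism(x, y, B = 150, seed = 3)
  expect_gt(b$apparent_c, b$corrected_c)   # optimism is positive
  expect_gt(b$corrected_c, 0.4)
  expect_lt(b$corrected_c, 0.6)
  # determinism under the seed
  b2 <- bootstrap_optimism(x, y, B = 150, seed = 3)
  expect_identical(b$corrected_c, b2$corrected_c)
  b3 <- bootstrap_optimism(x, y, B = 150, seed = 4)
  expect_false(identical(b$corrected_c, b3$corrected_c))
})

test_that("a dominant predictor leaves little optimism to correct", {
  set.seed(8)
  n <- 200
  y <- rep(0:1, length.out = n)
  x <- data.frame(strong = rnorm(n, 2.5 * y))
  b <- bootstrap_optimism(x, y, B = 100, seed = 5)
  expect_lt(b$apparent_c - b$corrected_c, 0.02)
  expect_gt(b$corrected_c, 0.9)
})

test_that("compare_models produces the two-nested-model report", {
  set.seed(9)
  n <- 160
  co <- generate_cohort(cohort_config(n_subjects = n, seed = 10),
                        volumes = FALSE)$cohort
  # plant a radiomic effect; clinical covariates stay null by construction
  co$rad_score <- rnorm(n, 1.2 * co$label)
  cm <- compare_models(co, B = 150, seed = 11)
  expect_s3_class(cm, "pdl1_model_comparison")
  expect_gt(cm$model2$c_statistic, cm$model1$c_statistic)
  expect_gt(cm$bootstrap$corrected_c[2], cm$bootstrap$corrected_c[1])
  expect_lt(cm$delong$p, 0.05)
  expect_identical(cm$model2$or_table$term,
                   c("age_le_cutoff", "female", "ever_smoker",
                     "egfr_mutation", "radscore_positive"))
  tab <- comparison_table(cm)
  expect_true(all(c("c_statistic", "bootstrap_corrected_c", "delong_p") %in%
                  tab$term))
  expect_output(print(cm), "Bootstrap")
  # apparent c never decreases when nesting adds a covariate
  expect_gte(cm$bootstrap$apparent_c[2], cm$bootstrap$apparent_c[1])
})

test_that("sparse clinical tables fall back to Fisher's exact test", {
  x <- c(rep("a", 3), rep("b", 37))
  y <- c(1, 1, 0, rbinom(37, 1, 0.5))
  r <- categorical_group_test(x, y)
  expect_identical(r$method, "fisher")
  r2 <- categorical_group_test(rep(c("a", "b"), 50), rbinom(100, 1, 0.5))
  expect_identical(r2$method, "chisq")
})
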