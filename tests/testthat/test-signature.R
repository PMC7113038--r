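# Rad-score evaluation, the frozen published signature, Youden cutoff,
# dichotomization.

test_that("the published signature reproduces its printed arithmetic", {
  sig <- published_signature()
  feats <- names(sig$coefficients)
  zero <- setNames(rep(0, 4), feats)
  expect_equal(rad_score(sig, zero), -1.59423, tolerance = 1e-12)
  unit <- setNames(rep(1, 4), feats)
  expect_equal(rad_score(sig, unit), -11.46557, tolerance = 1e-10)
  expect_equal(sig$cutoff, -0.715)
  expect_setequal(feats, c("Texture_GLCM_ASM", "Texture_GLRLM_RV",
                           "Texture_GLRLM_RE", "Texture_GLRLM_SRHGE"))
})

test_that("rad_score is exactly linear and order-independent", {
  sig <- published_signature()
  set.seed(1)
  f <- setNames(runif(4), names(sig$coefficients))
  s0 <- rad_score(sig, f)
  f2 <- f; f2[2] <- 2 * f[2]
  expect_equal(rad_score(sig, f2) - s0,
               sig$coefficients[[2]] * f[[2]], tolerance = 1e-12)
  expect_equal(rad_score(sig, rev(f)), s0)
  # data-frame evaluation matches elementwise evaluation
  df <- as.data.frame(rbind(f, f2))
  expect_equal(rad_score(sig, df), c(s0, rad_score(sig, f2)))
  expect_error(rad_score(sig, f[-1]), "Texture_GLCM_ASM")
})

test_that("signature JSON round trip preserves every field", {
  sig <- rad_signature(-1.2, c(Texture_GLRLM_RV = 0.5,
                               Texture_GLCM_IDM = -2), cutoff = 0.3,
                       name = "toy")
  td <- withr::local_tempdir()
  write_signature_json(sig, file.path(td, "s.json"))
  r <- read_signature_json(file.path(td, "s.json"))
  expect_equal(r$intercept, sig$intercept)
  expect_equal(r$coefficients, sig$coefficients)
  expect_equal(r$cutoff, sig$cutoff)
  expect_error(rad_signature(0, c(NotAFeature = 1)), "unknown feature")
})

test_that("Youden cutoff matches exhaustive enumeration on random data", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(8:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 2)
    if (length(unique(scores)) < 2) next
    got <- youden_cutoff(scores, labels)
    ref <- oracle_youden(scores, labels)
    expect_equal(got$cutoff, ref$cutoff)
    expect_equal(got$youden, ref$youden)
    expect_equal(got$sensitivity, ref$sensitivity)
    expect_equal(got$specificity, ref$specificity)
  }
})

test_that("Youden cutoff honors separation, ties and symmetry contracts", {
  # perfect separation
  r <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 0.2); expect_lt(r$cutoff, 0.8)
  expect_equal(r$auc, 1)
  # equal-Youden ties break toward the higher cutoff (higher specificity)
  r2 <- youden_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$cutoff, 3.5)
  # label swap mirrors the AUC
  sc <- c(0.3, 0.7, 0.2, 0.9, 0.5)
  la <- c(0, 1, 0, 1, 1)
  expect_equal(youden_cutoff(sc, la)$auc, 1 - youden_cutoff(sc, 1 - la)$auc)
  expect_error(youden_cutoff(rep(1, 4), c(0, 1, 0, 1)), "identical")
  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the ROC AUC equals the midrank concordance statistic", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- sample(seq(0, 1, 0.05), 40, replace = TRUE)  # plenty of ties
  labels <- rbinom(40, 1, 0.4)
  a <- auc_concordance(scores, labels)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE,
                                                 direction = "<"))),
               tolerance = 1e-12)
  expect_equal(youden_cutoff(scores, labels)$auc, a, tolerance = 1e-12)
})

test_that("dichotomization follows the documented strict conventions", {
  # Rad-score: strictly-greater-than rule
  expect_equal(dichotomize(c(-0.70, -0.715, -0.72), -0.715, "gt"),
               c(1L, 0L, 0L))
  # age: at-or-below stratum includes the cutoff
  expect_equal(dichotomize(c(58, 59, 60), 59, "le"), c(1L, 1L, 0L))
})
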