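# Synthetic phantom generator: determinism, geometry, mask perturbation,
# cohort structure.

test_that("phantom generation is a pure function of (spec, label, seed)", {
  sp <- tiny_phantom_spec()
  v1 <- generate_phantom(sp, 1, seed = 42)
  v2 <- generate_phantom(sp, 1, seed = 42)
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$mask, v2$mask)
  v3 <- generate_phantom(sp, 1, seed = 43)
  expect_false(identical(v1$intensities, v3$intensities))
})

test_that("with zero effect the two labels are generated identically", {
  sp <- tiny_phantom_spec()
  v0 <- generate_phantom(sp, 0, seed = 9, effect_homogeneity = 0)
  v1 <- generate_phantom(sp, 1, seed = 9, effect_homogeneity = 0)
  expect_identical(v0$intensities, v1$intensities)
  expect_identical(v0$mask, v1$mask)
})

test_that("unlobulated ellipsoid mask volume matches the analytic volume", {
  sp <- phantom_spec(grid_shape = c(28, 28, 28), spacing_mm = c(1, 1, 1),
                     radii_mm = c(10, 10, 10), lobulation_amp = 0)
  v <- generate_phantom(sp, 0, seed = 1)
  vol <- sum(v$mask)                     # spacing 1 => mm^3
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.2)
})

test_that("masks are single connected components and background is lung-like", {
  for (s in 1:4) {
    v <- generate_phantom(tiny_phantom_spec(lobulation_amp = 0.2), s %% 2,
                          seed = 100 + s)
    expect_true(radpdl1:::is_single_component6(v$mask))
    bg <- v$intensities[!v$mask & !radpdl1:::dilate6(v$mask)]
    expect_lt(abs(mean(bg) - (-800)), 15)
  }
})

test_that("a tumor that cannot fit raises a sizing error", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16),
                            spacing_mm = c(1, 1, 1), radii_mm = c(12, 8, 8)),
               "sizing error")
})

test_that("mask perturbation honors the magnitude contract", {
  sp <- c(1, 1, 1)
  ball <- digital_ball(10)$mask
  expect_identical(perturb_mask(ball, sp, 0, seed = 1), ball)
  p1 <- perturb_mask(ball, sp, 1, seed = 1)
  expect_gt(dice(ball, p1), 0.8)
  expect_true(any(p1 != perturb_mask(ball, sp, 1, seed = 2)))
  expect_true(radpdl1:::is_single_component6(p1))
  # expected Dice decreases with magnitude
  d_small <- mean(sapply(1:5, function(s) dice(ball, perturb_mask(ball, sp, 0.5, s))))
  d_large <- mean(sapply(1:5, function(s) dice(ball, perturb_mask(ball, sp, 2.5, s))))
  expect_gt(d_small, d_large)
})

test_that("cohort tables are reproducible and validate their inputs", {
  cfg <- cohort_config(n_subjects = 20, seed = 5)
  a <- generate_cohort(cfg, volumes = FALSE)$cohort
  b <- generate_cohort(cfg, volumes = FALSE)$cohort
  expect_identical(a, b)
  expect_error(cohort_config(n_subjects = 9), "at least 10")
  expect_error(cohort_config(prevalence = 1.2), "prevalence")
  expect_error(cohort_config(smoking_probs = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("clinical covariates are independent of the label by construction", {
  cfg <- cohort_config(n_subjects = 2000, seed = 78)
  co <- generate_cohort(cfg, volumes = FALSE)$cohort
  expect_gt(chisq.test(table(co$egfr, co$label))$p.value, 0.01)
  expect_gt(chisq.test(table(co$sex, co$label))$p.value, 0.01)
  expect_gt(t.test(age ~ label, data = co)$p.value, 0.01)
})

test_that("positives count is Binomial(n, prevalence) with the right mean", {
  counts <- vapply(1:150, function(s)
    sum(generate_cohort(cohort_config(seed = s), volumes = FALSE)$cohort$label),
    numeric(1))
  # mean of Binomial(153, 53/153) is 53; se of the mean over 150 replicates
  # is about 0.5
  expect_lt(abs(mean(counts) - 53), 2)
  expect_gt(var(counts), 10)   # genuinely random, not fixed margins
})

test_that("full cohort generation yields paired reader masks per subject", {
  cfg <- cohort_config(n_subjects = 10, prevalence = 0.4, seed = 3,
                       phantom = tiny_phantom_spec())
  sim <- generate_cohort(cfg)
  expect_length(sim$volumes, 10)
  expect_length(sim$masks_reader2, 10)
  for (i in c(1, 5, 10)) {
    expect_identical(dim(sim$masks_reader2[[i]]), dim(sim$volumes[[i]]$mask))
    expect_gt(dice(sim$volumes[[i]]$mask, sim$masks_reader2[[i]]), 0.6)
  }
})
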