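# First-order, gradient, moment and texture features: hand-computed
# examples and brute-force oracle equivalence on small random volumes.

test_that("discretization follows the equal-width, last-bin-closed rule", {
  expect_identical(discretize(make_voi(c(0, 100)), 2)$levels[, 1, 1], c(1L, 2L))
  expect_identical(discretize(make_voi(c(0, 50, 100)), 2)$levels[, 1, 1],
                   c(1L, 2L, 2L))
  d <- discretize(make_voi(rep(7, 5)), 8)
  expect_true(d$degenerate)
  expect_true(all(d$levels[, 1, 1] == 1L))
  expect_error(discretize(make_voi(c(0, 1)), 1), "at least 2")
})

test_that("histogram features match their definitions", {
  # constant VOI: flagged, moments zeroed, single-level histogram
  h <- histogram_features(make_voi(rep(3, 10)), G = 8)
  expect_true(attr(h, "degenerate"))
  expect_equal(unname(h[c("Texture_Histo_Skewness", "Texture_Histo_ExcessKurtosis",
                          "Texture_Histo_SD")]), c(0, 0, 0))
  expect_equal(unname(h["Texture_Histo_Energy"]), 1)
  expect_equal(unname(h["Texture_Histo_Entropy"]), 0)
  # two equal-count levels: 1 bit of entropy
  h2 <- histogram_features(make_voi(c(0, 0, 100, 100)), G = 2)
  expect_equal(unname(h2["Texture_Histo_Entropy"]), 1)
  expect_equal(unname(h2["Texture_Histo_Energy"]), 0.5)
  # linear-interpolation percentiles
  h3 <- histogram_features(make_voi(1:10), G = 2)
  expect_equal(unname(h3["Texture_Percentile_50"]), 5.5)
  expect_equal(unname(h3["Texture_Histo_VoxelCount"]), 10)
  expect_error(histogram_features(make_voi(5, dims = c(1, 1, 1))), "at least 2")
})

test_that("gradient features are exact on linear ramps and isotropic", {
  dims <- c(12, 12, 12)
  ramp_x <- make_voi(rep(3 * (1:12), times = 144), dims)
  g <- gradient_features(ramp_x)
  expect_equal(unname(g), c(3, 0))
  # same ramp along y (a 90-degree rotation): identical magnitude stats
  ramp_y <- make_voi(rep(rep(3 * (1:12), each = 12), times = 12), dims)
  expect_equal(gradient_features(ramp_y), g)
  # spacing scales the mm-denominator
  ramp2 <- volume_with_mask(ramp_x$intensities, ramp_x$mask, c(2, 1, 1))
  expect_equal(unname(gradient_features(ramp2)[1]), 1.5)
  flat <- make_voi(rep(5, prod(dims)), dims)
  expect_equal(unname(gradient_features(flat)), c(0, 0))
})

test_that("GLCM features match hand-enumerated pair counts", {
  # alternating 1-D sequence: p(1,2) = p(2,1) = 0.5
  g <- glcm_features(discretize(make_voi(c(0, 100, 0, 100)), 2))
  expect_equal(unname(g["Texture_GLCM_ASM"]), 0.5)
  expect_equal(unname(g["Texture_GLCM_Contrast"]), 1)
  expect_equal(unname(g["Texture_GLCM_Correlation"]), -1)
  expect_equal(unname(g["Texture_GLCM_Entropy"]), 1)
  # constant texture: maximal concentration
  g0 <- glcm_features(discretize(make_voi(rep(4, 8), c(2, 2, 2)), 8))
  expect_equal(unname(g0[c("Texture_GLCM_ASM", "Texture_GLCM_Contrast",
                           "Texture_GLCM_Entropy")]), c(1, 0, 0))
  expect_true(attr(g0, "degenerate"))
})

test_that("GLRLM features match single-run hand computations", {
  d1 <- discretize(make_voi(c(5, 5, 5)), 2)   # one run of length 3
  f1 <- radpdl1:::glrlm_features_one(glrlm_matrix(d1, c(1, 0, 0)), 3)
  expect_equal(f1[c(1, 2, 11, 12, 13)], c(1 / 9, 9, 1 / 3, 0, 0))
  d2 <- discretize(make_voi(c(0, 0, 100)), 2) # runs (1,2) and (2,1)
  f2 <- radpdl1:::glrlm_features_one(glrlm_matrix(d2, c(1, 0, 0)), 3)
  expect_equal(f2[c(1, 2, 11)], c(0.625, 2.5, 2 / 3))
})

test_that("GLCM and GLRLM agree with brute-force oracles on random volumes", {
  for (s in 1:15) {
    v <- random_voi(c(5, 5, 5), seed = s, mask_prob = if (s %% 2) 1 else 0.8)
    dv <- discretize(v, 4)
    expect_equal(glcm_matrix(dv), oracle_glcm_matrix(dv), tolerance = 1e-12)
    expect_equal(glcm_features(dv), oracle_glcm_features(dv),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(glrlm_features(dv), oracle_glrlm_features(dv),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("moment invariants match the closed form for a uniform ball", {
  ball <- digital_ball(10)
  m <- moment_features(ball)
  # uniform ball: second-moment matrix (R^2/5) I, so J1 = 3 R^2 / 5
  expect_lt(abs(m[["Texture_Moment_J1"]] - 60) / 60, 0.02)
  expect_lt(abs(m[["Texture_Moment_J3"]] - 20^3) / 20^3, 0.06)
  # doubling the spacing scales J1 by 4 exactly (dimensional analysis)
  m2 <- moment_features(volume_with_mask(ball$intensities, ball$mask,
                                         c(2, 2, 2)))
  expect_equal(m2[["Texture_Moment_J1"]] / m[["Texture_Moment_J1"]], 4)
  # negative total intensity triggers the min-shift path with a flag
  neg <- volume_with_mask(array(-5, dim(ball$mask)), ball$mask, c(1, 1, 1))
  mn <- moment_features(neg)
  expect_true(attr(mn, "shifted_weights"))
  expect_true(all(is.finite(mn)))
})

test_that("extract_features returns the full finite catalogue deterministically", {
  v <- generate_phantom(tiny_phantom_spec(), 1, seed = 12)
  f <- extract_features(v)
  expect_identical(names(f), radiomic_feature_names())
  expect_length(f, 58L)
  expect_true(all(is.finite(f)))
  expect_equal(extract_features(v), f)
  tab <- table(radiomic_catalogue()$category)[c("histogram", "gradient",
                                                "glcm", "glrlm", "moment",
                                                "shape", "fractal")]
  expect_equal(unname(as.integer(tab)), c(15L, 2L, 13L, 13L, 3L, 11L, 1L))
})

test_that("degenerate constant VOI extracts with flags instead of failing", {
  dims <- c(8, 8, 8)
  m <- array(FALSE, dims); m[3:6, 3:6, 3:6] <- TRUE
  v <- volume_with_mask(array(12, dims), m, c(1, 1, 1))
  f <- extract_features(v)
  expect_true("degenerate_texture" %in% attr(f, "flags"))
  expect_equal(unname(f["Texture_GLCM_ASM"]), 1)
  expect_true(all(is.finite(f)))
})
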