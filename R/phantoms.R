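# Synthetic 3-D tumor phantoms: lobulated ellipsoids with Gaussian-random-
# field texture, an optional low-attenuation (necrotic/cavitary) core, a
# second-reader mask perturbation model, and full labeled cohorts.

#' Specification of a synthetic tumor phantom
#'
#' Parameters of one synthetic tumor: a lobulated ellipsoid carrying a
#' stationary Gaussian-random-field texture on a lung-like background, with
#' an optional low-attenuation core (the necrosis/cavitation complex seen in
#' heterogeneous tumors). The PD-L1-positive phenotype is emulated by
#' [generate_phantom()] as a more homogeneous tumor: longer texture
#' correlation lengths in the bulk and (mainly) in the core.
#'
#' @param grid_shape Integer voxels per axis (length 3, each >= 16).
#' @param spacing_mm Voxel size per axis in mm (> 0).
#' @param radii_mm Ellipsoid semi-axes in mm (> 0).
#' @param base_hu Mean tumor attenuation (HU).
#' @param texture_corr_len_mm Correlation length of the tumor-bulk texture
#'   field (mm).
#' @param texture_sd_hu SD of the bulk texture field (HU).
#' @param necrosis_prob Probability of a low-attenuation core.
#' @param necrosis_hu Mean core attenuation (HU).
#' @param necrosis_sd_hu SD of the core texture field (HU).
#' @param necrosis_corr_len_mm Correlation length of the core texture (mm).
#' @param necrosis_radius_frac Core semi-axes as a fraction of the tumor
#'   semi-axes.
#' @param noise_sd_hu SD of uncorrelated voxel noise (HU).
#' @param lobulation_amp Amplitude of the low-order spherical-harmonic
#'   radial perturbation, as a fraction of the local radius.
#' @param background_hu Lung-like background attenuation (HU).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         spacing_mm = c(1.25, 1.25, 1.25),
                         radii_mm = c(10, 8.5, 7),
                         base_hu = 45,
                         texture_corr_len_mm = 3.0,
                         texture_sd_hu = 50,
                         necrosis_prob = 0.95,
                         necrosis_hu = -450,
                         necrosis_sd_hu = 110,
                         necrosis_corr_len_mm = 1.1,
                         necrosis_radius_frac = 0.74,
                         noise_sd_hu = 3,
                         lobulation_amp = 0.12,
                         background_hu = -800) {
  spec <- list(grid_shape = as.integer(rep_len(grid_shape, 3L)),
               spacing_mm = as.numeric(rep_len(spacing_mm, 3L)),
               radii_mm = as.numeric(rep_len(radii_mm, 3L)),
               base_hu = base_hu,
               texture_corr_len_mm = texture_corr_len_mm,
               texture_sd_hu = texture_sd_hu,
               necrosis_prob = necrosis_prob,
               necrosis_hu = necrosis_hu,
               necrosis_sd_hu = necrosis_sd_hu,
               necrosis_corr_len_mm = necrosis_corr_len_mm,
               necrosis_radius_frac = necrosis_radius_frac,
               noise_sd_hu = noise_sd_hu,
               lobulation_amp = lobulation_amp,
               background_hu = background_hu)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(grid_shape < 16L)) stop("'grid_shape' must be at least 16 voxels per axis")
    if (any(spacing_mm <= 0) || any(radii_mm <= 0))
      stop("lengths must be strictly positive")
    stopifnot(texture_corr_len_mm > 0, texture_sd_hu >= 0,
              necrosis_corr_len_mm > 0, necrosis_sd_hu >= 0,
              noise_sd_hu >= 0, lobulation_amp >= 0,
              necrosis_radius_frac > 0, necrosis_radius_frac < 1)
    if (necrosis_prob < 0 || necrosis_prob > 1)
      stop("'necrosis_prob' must be in [0, 1]")
    # worst-case tumor extent (lobulation can inflate the radius)
    reach <- radii_mm * (1 + 3.5 * lobulation_amp)
    half_box <- grid_shape * spacing_mm / 2
    if (any(reach >= half_box - spacing_mm))
      stop("sizing error: tumor (radii + lobulation) does not fit inside the grid")
  })
  invisible(spec)
}

# Gaussian random field with correlation length `len_mm`: separable
# Gaussian smoothing of white noise, standardized over the voxels in
# `over` (default: whole grid).
grf3d <- function(dim, spacing_mm, len_mm, sd, over = NULL) {
  f <- array(stats::rnorm(prod(dim)), dim)
  f <- smooth3d(f, len_mm / spacing_mm)
  ref <- if (is.null(over)) f else f[over]
  s <- stats::sd(ref)
  if (s > 0) f <- (f - mean(ref)) / s
  f * sd
}

# Gaussian-copula random field: a correlated field whose values over the
# voxel set `over` are replaced, in rank order, by the exact quantiles of
# N(mean, sd). Every realization therefore has the identical marginal
# value multiset (given the size of `over`); the correlation length
# changes only the spatial arrangement. This is what lets the phantom
# cohort plant purely *spatial* (texture) group differences with
# first-order histogram statistics exchangeable between labels.
copula_field <- function(dim, spacing_mm, len_mm, mean, sd, over) {
  f <- array(stats::rnorm(prod(dim)), dim)
  f <- smooth3d(f, len_mm / spacing_mm)
  n <- sum(over)
  m0 <- mean(f[over]); s0 <- stats::sd(f[over])
  r <- rank(f[over], ties.method = "first")
  # outside `over` (used only for partial-volume blending at the tumor
  # boundary) the field is carried over on the affine scale
  if (s0 > 0) f <- mean + sd * (f - m0) / s0
  f[over] <- mean + sd * stats::qnorm((r - 0.5) / n)
  f
}

# Low-order (degree 2-3) real-harmonic radial perturbation evaluated at the
# unit directions `n` (matrix of rows), standardized to unit SD over the
# supplied directions.
harmonic_perturbation <- function(n, coefs) {
  x <- n[, 1]; y <- n[, 2]; z <- n[, 3]
  basis <- cbind(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
                 z * (5 * z^2 - 3), x * (5 * z^2 - 1), y * (5 * z^2 - 1),
                 z * (x^2 - y^2), x * y * z, x * (x^2 - 3 * y^2),
                 y * (3 * x^2 - y^2))
  f <- drop(basis %*% coefs)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

# Modify a phantom spec for the label-dependent homogeneity effect:
# PD-L1-positive tumors are smoother (longer texture correlation in bulk
# and, mainly, in the core). The core probability and all HU marginals are
# label-independent, so first-order statistics stay exchangeable; with
# effect = 0 the two labels share one distribution entirely.
apply_label_effect <- function(spec, label, effect) {
  stopifnot(effect >= 0)
  pos <- label > 0
  bulk_f <- 1 + 0.07 * effect
  core_f <- 1 + 0.40 * effect
  spec$texture_corr_len_mm <- spec$texture_corr_len_mm *
    (if (pos) bulk_f else 1 / bulk_f)
  spec$necrosis_corr_len_mm <- spec$necrosis_corr_len_mm *
    (if (pos) core_f else 1 / core_f)
  spec
}

#' Generate a synthetic tumor phantom
#'
#' Deterministic given `(spec, label, seed, effect_homogeneity)`. The tumor
#' is a lobulated ellipsoid (radial spherical-harmonic perturbation) filled
#' with correlated Gaussian texture around `base_hu`; with probability
#' `necrosis_prob` a low-attenuation textured core is embedded at a random
#' interior position. Voxels outside the mask are lung-like background. The
#' PD-L1-positive phenotype draws longer texture correlation lengths and a
#' lower core probability (a more homogeneous tumor); the HU marginals of
#' the texture fields are label-independent, so the planted effect is
#' spatial, not first-order.
#'
#' @param spec A [phantom_spec()].
#' @param label Binary PD-L1 label (0/1).
#' @param seed Integer seed.
#' @param effect_homogeneity Non-negative effect-size knob; 0 makes the two
#'   labels exchangeable.
#' @return A [volume_with_mask()] object with attributes `"necrotic"` and
#'   `"label"`.
#' @export
generate_phantom <- function(spec, label, seed, effect_homogeneity = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- check_binary_labels(label)
  spec <- apply_label_effect(spec, label, effect_homogeneity)
  validate_phantom_spec(spec)
  with_seed(seed, {
    d <- spec$grid_shape
    sp <- spec$spacing_mm
    ctr <- (d + 1) / 2 * sp
    idx <- arrayInd(seq_len(prod(d)), d)
    xyz <- sweep(idx, 2, sp, `*`)
    rel <- sweep(xyz, 2, ctr)
    # normalized ellipsoid radius and unit directions
    rn <- sqrt(rowSums(sweep(rel, 2, spec$radii_mm, `/`)^2))
    rr <- sqrt(rowSums(rel^2))
    nhat <- rel / pmax(rr, 1e-9)
    pert <- harmonic_perturbation(nhat, stats::rnorm(12L))
    mask_v <- rn <= 1 + spec$lobulation_amp * pert
    mask_v[rr < 1e-9] <- TRUE
    mask <- array(mask_v, d)
    mask <- largest_component6(mask)
    if (on_border(mask)) stop("sizing error: tumor touches the grid border")
    # core region decided first so the bulk marginal can be pinned over
    # exactly the voxels that will keep bulk values
    necrotic <- stats::runif(1) < spec$necrosis_prob
    core <- array(FALSE, d)
    if (necrotic) {
      shift <- stats::runif(3, -0.3, 0.3) * spec$radii_mm
      core_radii <- spec$necrosis_radius_frac * spec$radii_mm
      rc <- sqrt(rowSums(sweep(sweep(rel, 2, shift), 2, core_radii, `/`)^2))
      core <- array(rc <= 1, d) & mask
      if (sum(core) < 2L) core[] <- FALSE
    }
    bulk_region <- mask & !core
    tumor <- copula_field(d, sp, spec$texture_corr_len_mm, spec$base_hu,
                          spec$texture_sd_hu, over = bulk_region)
    if (any(core)) {
      core_field <- copula_field(d, sp, spec$necrosis_corr_len_mm,
                                 spec$necrosis_hu, spec$necrosis_sd_hu,
                                 over = core)
      tumor[core] <- core_field[core]
    }
    # partial-volume transition: blend tumor into the lung background over
    # ~1 voxel at the boundary, as a CT scanner would; the VOI thereby
    # contains a thin rim of intermediate/low HU voxels on every subject
    w <- smooth3d(array(as.numeric(mask), d), 0.8)
    vol <- w * tumor + (1 - w) * spec$background_hu
    vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd_hu), d)
    out <- volume_with_mask(vol, mask, sp)
    attr(out, "necrotic") <- necrotic
    attr(out, "label") <- label
    out
  })
}

on_border <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
}

#' Perturb a tumor mask to emulate a second reader's segmentation
#'
#' Applies a sequence of one-voxel boundary edits (dilations and erosions)
#' selected by a smoothed random field, so that added and removed regions
#' are spatially coherent like human re-segmentation differences. The
#' expected Dice overlap with the input decreases monotonically as
#' `magnitude_mm` grows; magnitude 0 returns the mask unchanged. The result
#' is reduced to its largest connected component.
#'
#' @param mask 3-D logical array (non-empty).
#' @param spacing_mm Voxel spacing (mm).
#' @param magnitude_mm Perturbation magnitude in mm (approximate boundary
#'   displacement).
#' @param seed Integer seed.
#' @return Perturbed logical mask of the same dimensions.
#' @export
perturb_mask <- function(mask, spacing_mm, magnitude_mm, seed) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, any(mask),
            magnitude_mm >= 0)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (magnitude_mm == 0) return(mask)
  step_mm <- mean(spacing_mm)
  n_ops <- ceiling(magnitude_mm / step_mm)
  frac <- (magnitude_mm / step_mm) / n_ops   # partial strength per op
  thr <- stats::qnorm(1 - frac / 2)
  with_seed(seed, {
    out <- mask
    for (op in seq_len(n_ops)) {
      u <- grf3d(dim(mask), spacing_mm, 2.5 * step_mm, 1)
      grow <- dilate6(out) & !out & (u > thr)
      shrink <- boundary_voxels(out) & (u < -thr)
      cand <- (out | grow) & !shrink
      if (!any(cand)) {
        # perturbation emptied the mask: retry this op with growth only
        cand <- out | grow
        if (!any(cand)) stop("mask perturbation emptied the mask")
      }
      out <- cand
    }
    largest_component6(out)
  })
}

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the study conditions of the analysis this package
#' reimplements: 153 subjects with 53/153 PD-L1 prevalence, clinical
#' covariates (age, sex, smoking, EGFR) drawn independently of the label,
#' and a planted tumor-homogeneity effect in the imaging.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param prevalence PD-L1-positive fraction, in (0, 1).
#' @param age_mean,age_sd Age distribution (years).
#' @param male_fraction Probability of male sex.
#' @param smoking_probs Probabilities for current/past/never smoking
#'   (must sum to 1).
#' @param egfr_fraction Probability of an EGFR mutation.
#' @param effect_homogeneity Planted homogeneity effect size (0 = none).
#' @param phantom A [phantom_spec()] template; per-subject size and
#'   attenuation are jittered around it (label-independently).
#' @param reader2_magnitude_mm Mask perturbation magnitude for the emulated
#'   second reader.
#' @param seed Master seed; every downstream draw derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 153L,
                          prevalence = 53 / 153,
                          age_mean = 64.6, age_sd = 10.7,
                          male_fraction = 99 / 153,
                          smoking_probs = c(current = 27, past = 59,
                                            never = 67) / 153,
                          egfr_fraction = 50 / 153,
                          effect_homogeneity = 1,
                          phantom = phantom_spec(),
                          reader2_magnitude_mm = 0.6,
                          seed = 1L) {
  if (n_subjects < 10L)
    stop("'n_subjects' must be at least 10 (downstream statistics are undefined below that)")
  if (prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must be strictly inside (0, 1)")
  if (abs(sum(smoking_probs) - 1) > 1e-8)
    stop("'smoking_probs' must sum to 1")
  stopifnot(age_sd > 0, male_fraction >= 0, male_fraction <= 1,
            egfr_fraction >= 0, egfr_fraction <= 1,
            effect_homogeneity >= 0, reader2_magnitude_mm >= 0,
            inherits(phantom, "phantom_spec"))
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 age_mean = age_mean, age_sd = age_sd,
                 male_fraction = male_fraction,
                 smoking_probs = smoking_probs,
                 egfr_fraction = egfr_fraction,
                 effect_homogeneity = effect_homogeneity,
                 phantom = phantom,
                 reader2_magnitude_mm = reader2_magnitude_mm,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic labeled cohort
#'
#' Draws labels as Bernoulli(prevalence) and all clinical covariates
#' independently of the label (emulating a cohort in which no clinical
#' variable separates the groups), then generates one tumor phantom per
#' subject plus an emulated second-reader mask. Per-subject tumor size and
#' attenuation are jittered label-independently. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param volumes If `FALSE`, only the clinical table is generated (fast
#'   path for covariate-level checks on large `n`).
#' @return List with `cohort` (a `cohort_table` data frame), and when
#'   `volumes = TRUE`: `volumes` (list of [volume_with_mask()]) and
#'   `masks_reader2` (list of logical arrays).
#' @export
generate_cohort <- function(config, volumes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  seeds <- derive_seeds(config$seed, 4L * n + 1L)
  cohort <- with_seed(seeds[1L], {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      label = stats::rbinom(n, 1L, config$prevalence),
      age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
      sex = ifelse(stats::runif(n) < config$male_fraction, "male", "female"),
      smoking = sample(names(config$smoking_probs), n, replace = TRUE,
                       prob = config$smoking_probs),
      egfr = as.integer(stats::runif(n) < config$egfr_fraction),
      stringsAsFactors = FALSE)
  })
  cohort <- validate_cohort_table(cohort)
  if (!volumes) return(list(cohort = cohort))
  vols <- vector("list", n)
  masks2 <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- jitter_phantom_spec(config$phantom, seeds[n + i])
    vols[[i]] <- generate_phantom(spec_i, cohort$label[i], seeds[2L * n + i],
                                  config$effect_homogeneity)
    masks2[[i]] <- perturb_mask(vols[[i]]$mask, spec_i$spacing_mm,
                                config$reader2_magnitude_mm,
                                seeds[3L * n + 1L + i])
  }
  names(vols) <- names(masks2) <- cohort$subject_id
  list(cohort = cohort, volumes = vols, masks_reader2 = masks2)
}

# Label-independent per-subject variability: overall size, per-axis
# anisotropy, mean attenuation, and texture/core parameters. This is what
# gives the cohort realistic between-subject feature variance (without it,
# the copula fields would make subjects so alike that interobserver ICCs
# are meaningless: ICC compares reader disagreement against between-subject
# spread).
jitter_phantom_spec <- function(spec, seed) {
  with_seed(seed, {
    scale <- exp(stats::rnorm(1, 0, 0.18))
    aniso <- exp(stats::rnorm(3, 0, 0.10))
    spec$radii_mm <- spec$radii_mm * scale * aniso
    # keep the jittered tumor inside the grid
    reach_max <- (min(spec$grid_shape * spec$spacing_mm) / 2 - 2 * max(spec$spacing_mm)) /
      (1 + 3.5 * spec$lobulation_amp)
    spec$radii_mm <- pmin(spec$radii_mm, reach_max)
    spec$base_hu <- spec$base_hu + stats::rnorm(1, 0, 20)
    spec$texture_sd_hu <- spec$texture_sd_hu * exp(stats::rnorm(1, 0, 0.15))
    spec$texture_corr_len_mm <- spec$texture_corr_len_mm *
      exp(stats::rnorm(1, 0, 0.25))
    spec$necrosis_corr_len_mm <- spec$necrosis_corr_len_mm *
      exp(stats::rnorm(1, 0, 0.35))
    spec$necrosis_hu <- spec$necrosis_hu + stats::rnorm(1, 0, 50)
    spec$necrosis_sd_hu <- spec$necrosis_sd_hu * exp(stats::rnorm(1, 0, 0.15))
    spec$necrosis_radius_frac <- min(0.92, spec$necrosis_radius_frac *
                                       exp(stats::rnorm(1, 0, 0.10)))
    spec
  })
}
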