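---
title: "Methods: CT radiomics, Rad-score construction and model validation on synthetic tumor phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomics, Rad-score construction and model validation on synthetic tumor phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpdl1)
```

## Scope and scientific question

This package reimplements, as tested reusable code, a CT-radiomics analysis
for predicting PD-L1 positivity (tumor proportion score ≥ 50%) in advanced
lung adenocarcinoma: 58 radiomic features per segmented tumor, a three-step
feature selection ending in a LASSO-derived Rad-score, Youden-cutoff
dichotomization, and a comparison of clinical versus clinical-plus-radiomic
logistic models with internal (bootstrap) validation. The original cohort
(153 patients, 53 PD-L1-positive) is private hospital data; every stage is
therefore exercised on synthetic 3-D tumor phantoms whose statistical
structure matches what the analysis assumes. The published cohort-level
numbers are consequently *direction targets*, not reproduction targets:
what the synthetic experiments can and do show is that the pipeline
recovers a planted homogeneity effect, that its reliability filter behaves
like an interobserver study, and that the added radiomic model improves the
corrected c-index when — and only when — a real effect is present.

## The feature engine

All features are computed inside the tumor mask after cropping the volume
to the mask bounding box plus a 4-voxel margin (which makes every feature
exactly translation-invariant). Physical units are millimetres throughout;
features that need geometry consume the voxel spacing explicitly.

**Discretization.** Texture features use equal-width binning of the
in-mask intensity range into `G = 32` levels (last bin closed). The choice
of 32 is configurable; nothing in the vendor literature fixes it, and the
magnitude of the autocorrelation feature (~1000 on real cohorts) is
consistent with a few dozen levels. A constant VOI yields a single-level
discretization with a degeneracy flag rather than an error.

**Histogram (15).** Mean, SD, min, max and the 10/25/50/75/90/95
percentiles are raw-HU statistics (percentiles by linear interpolation
between order statistics); skewness and excess kurtosis are population
moments; energy and entropy are computed on the G-level discretized
histogram, so they are invariant to affine HU rescaling.

**Gradient (2).** Mean and SD of the 3-D central-difference gradient
magnitude (HU/mm) over in-mask voxels, computed on raw HU. In-mask voxels
at the tumor border see the lung background through the stencil, exactly
as on a real CT volume.

**GLCM (13).** Co-occurrences of in-mask voxel pairs at the 13 unique
distance-1 3-D offsets, symmetrized and pooled over directions before
feature computation. The pooled direction set is closed under the
octahedral group, which is what makes these features exactly invariant
under 90° grid rotations. `IDM` uses the squared-difference kernel and
`Homogeneity` the absolute-difference kernel (the catalogue lists both, so
they must be distinct). Correlation is defined as 0, with a flag, when the
marginal variance vanishes.

**GLRLM (13).** Run-length matrices are computed per direction (runs break
at out-of-mask voxels) and the 13 features are averaged feature-wise over
directions. Standard normalizations are used (`SRE = Σ r/j² / N_r`, etc.,
with `N_r` runs and `N_p` voxels). The vendor tool behind the original
analysis evidently uses a nonstandard normalization (its published
short-run emphases are orders of magnitude below the standard convention);
numeric parity with the published per-feature magnitudes is explicitly not
a goal — the tests instead prove equality with independent brute-force
implementations to 1e-10.

**Moments (3).** `J1/J2/J3` are the trace, sum of principal 2×2 minors,
and determinant of the intensity-weighted, volume-normalized central
second-moment matrix in mm coordinates — the three rotation invariants of
that matrix. If the total intensity weight is non-positive (possible in
HU), weights are min-shifted and flagged.

**Shape (11).** Volume is voxel count × voxel volume. Surface area is
estimated by the coarea identity `A = ∫ |∇u| dV` applied to a
Gaussian-smoothed (σ = 0.7 voxel) copy of the mask: unlike voxel-face
counting (up to +50% bias) or a fixed tetrahedral decomposition (not
symmetric under the octahedral group), this estimator is essentially
unbiased on digital balls of tumor-like radii (≤ ~1%) *and* exactly
invariant under 90° rotations. Sphericity `π^{1/3}(6V)^{2/3}/A` and
compactness `36πV²/A³` follow (both 1 for an ideal ball; a near-spherical
digital mask may exceed 1 by up to ~1% — estimator bias, documented rather
than clipped). Roundness is the PCA isotropy (geometric mean / maximum of
the three PCA SDs). Circularity takes the largest axis-aligned
cross-section (scanning all three axis orientations so the feature
survives grid rotations; clinically this is the axial section) and
divides the equivalent-area-circle diameter by the longest in-plane
diameter. The longest axes are maximum pairwise distances between boundary
voxel centres, the second restricted to the plane orthogonal to the first;
when several boundary pairs tie for the diameter, the second axis is
maximized over all tied directions, so the feature does not depend on grid
orientation.

**Fractal (1).** Box-counting dimension of the boundary voxel set over
dyadic scales 1–16 voxels, least-squares slope of log N against log(1/s),
clipped to [0, 3]. `N(s)` is averaged over the eight corner-anchored box
partitions of the bounding box, which removes the arbitrary dependence on
grid placement and makes the count exactly invariant under 90° rotations.
Two estimator facts worth knowing: a *closed* digital surface (e.g. a
cube's boundary) carries a positive closure term (`N(u) = 6u² − 12u + 8`
for the cube), which biases the small-scale slope above 2 — the unbiased
anchor case is an open flat patch, which measures exactly 2; and the
dimension responds to fine-scale boundary roughness, not to smooth
low-order lobulation (which instead lowers sphericity). The tests encode
both facts.

## The synthetic phantom cohort

Each phantom is a lobulated ellipsoid (low-order spherical-harmonic radial
perturbation, amplitude 0.12) on a −800 HU lung background, blended at the
boundary over ~1 voxel to emulate partial volume — without that transition
rim, sub-voxel segmentation differences produce wildly unrealistic feature
instability, and with it the VOI minimum sits near −800 HU as on real
contrast CT. The tumor interior carries two **Gaussian-copula random
fields**: a bulk field (mean 45 HU, SD 50 HU, correlation length 3 mm) and,
with probability 0.95, a low-attenuation core (necrosis/cavitation complex:
74% of the semi-axes, mean −450 HU, SD 110 HU, correlation length 1.1 mm).
A copula field is a smoothed white-noise field whose values are replaced,
in rank order, by the exact quantiles of the target normal — so every
subject's texture has the *identical marginal value set* and only the
spatial arrangement varies.

**The planted effect is purely spatial.** PD-L1-positive phantoms draw
longer correlation lengths (bulk ×1.07, core ×1.40 at the default
`effect_homogeneity = 1`; negatives the reciprocals), i.e. they are more
homogeneous tumors, the phenotype the original analysis associates with
PD-L1 expression. Because the marginals are pinned, no first-order
histogram feature carries label information by construction; at
`effect_homogeneity = 0` the two labels are generated from exactly the
same distribution (the tests assert bitwise identity). Core prevalence is
deliberately label-independent: any prevalence contrast leaks into the
per-VOI intensity range, hence into the equal-width binning, and from
there into essentially every feature — the published cohort shows no
first-order separation, so exchangeable marginals are the faithful choice.

Under standard texture definitions, smoothness raises ASM, IDM,
homogeneity, long-run emphasis, run variance and run entropy in the
positive group (all directions matching the published comparison table)
and necessarily *lowers* short-run emphases — the published table reports
positives higher on every run-length feature simultaneously, which no
standard-definition generator can reproduce; the shattered low-gray core
in negative phantoms brings the short-run high-gray emphasis to an
approximately null group difference, which is the achievable limit and is
what the tests assert.

**Between-subject heterogeneity** (label-independent): tumor size ±18%
log-scale with per-axis anisotropy, mean attenuation ±20 HU, texture SD
±15%, correlation lengths ±25–35% log-scale, core depth ±50 HU and size
±10%. This variance is what makes interobserver ICCs meaningful — with
marginals pinned and no subject heterogeneity, between-subject feature
variance collapses and any segmentation noise floors the ICC.

**Second reader.** `perturb_mask()` applies a sequence of one-voxel
boundary edits selected by a smoothed random field (spatially coherent
additions and removals, like human re-segmentation), with a threshold that
scales sub-voxel magnitudes. At the default 0.6 mm the emulated
interobserver study retains ~40 of 58 features at ICC > 0.75 with median
ICC ≈ 0.88 — qualitatively matching a real two-reader study in which most
features show good-to-excellent agreement and a minority drop out.

**What the phantoms do not emulate:** scanner/kernel physics, contrast
dynamics, vessels and bronchi, anatomic context, multi-lesion disease, and
any real biological link between texture and PD-L1 biology. Passing tests
demonstrate that the *pipeline* behaves correctly and recovers planted
effects of realistic size — not that the radiomic signature itself
transfers to patients.

## Cohort-level statistics

Labels are Bernoulli(53/153); age (64.6 ± 10.7 y), sex (64.7% male),
smoking (17.6/38.6/43.8% current/past/never) and EGFR status (32.7%
mutated) are drawn independently of the label, emulating the published
cohort in which no clinical covariate separated the groups.

**Selection.** Step 1 filters at ICC(2,1) > 0.75 (two-way random effects,
absolute agreement, single measure; negative raw ICCs are clamped to zero
before filtering, and the consistency form is available for sensitivity
analyses). Step 2 is a pooled-variance Student's t-test at α = 0.05 per
feature (the classic statistical-package default; Welch is available); no
multiplicity correction, as in the source methodology. Step 3 standardizes
the candidates, runs L1-penalized logistic regressions over 100
log-spaced λ from the data-derived maximum down by 1e-4, and averages the
validation AUC per λ over 100 repeats of stratified 3-fold
cross-validation; the chosen λ maximizes the mean AUC over all 300
validation folds (ties break toward the larger λ, i.e. the sparser
model — both the fold-averaged and repeat-averaged readings of "mean AUC"
coincide with this estimator). The final fit at the chosen λ on all data
gives raw-scale coefficients (the published signature's coefficient
magnitudes indicate a raw-scale formula), and the tests verify the
raw-scale score equals the penalized fit's link to 1e-10.

**Cutoffs.** The Youden cutoff scans midpoints between consecutive
distinct scores; classification is *strictly greater than* the cutoff;
equal-Youden ties resolve to the higher cutoff (higher specificity). Age
is dichotomized as an at-or-below stratum, with the cutoff derived by the
same Youden rule by default (the provenance of the published age cutoff of
59 is not documented; it is exposed as a parameter).

**Models.** Model 1 regresses the label on dichotomized age, female sex,
current-or-ex smoking and EGFR mutation (reference levels: older age,
male, never-smoker, wild type); Model 2 adds the dichotomized Rad-score.
c-statistics are midrank concordance AUCs of the linear predictors with
DeLong-variance CIs; the two models are compared with the paired DeLong
test (the software used in the original analysis implements exactly this
test). Internal validation follows the standard resample-refit optimism
bootstrap: stratified resamples (no single-class draws; plain resampling
with redraw available), shared across the two models so the percentile CI
of the c-difference reflects their pairing; corrected c = apparent c −
mean optimism.

## Numerical choices and degenerate inputs

* Constant VOI: degeneracy flag; skewness/kurtosis 0, energy 1, entropy 0,
  ASM 1, contrast 0; GLCM correlation 0 at zero marginal variance.
* Zero-variance reader tables: ICC defined 1 (perfect trivial agreement),
  flagged; single-category kappa undefined (`NA`), flagged.
* Zero within-class variance in the t-screen: p defined 1, flagged.
* No nonzero LASSO coefficients at the chosen λ: intercept-only signature
  with a warning, never an error.
* Perfect separation in a logistic fit: flagged, CIs suppressed.
* Identical paired scores in the DeLong test: p = 1 by convention.
* Masks are reduced to their largest 6-connected component; a tumor
  touching the grid border is a sizing error.

## Problem sizes used by the tests and acceptance script

The test suite runs the full three-step recovery study on 20 seeded
cohorts of 153 subjects at 32³ phantom grids with the cross-validation
repeated 25 times per cohort, plus a 100-volume brute-force oracle
comparison at ≤ 6³ and a 5000-permutation DeLong oracle at n = 30; the
acceptance script runs one full cohort analysis at the study conditions
(n = 153, 100 CV repeats, 1000 bootstrap resamples). These sizes were
chosen so the whole battery completes comfortably on a single CPU while
keeping every statistical check well-powered; scaling the phantom grid or
repeat counts up changes no defaults and no conclusions, only precision.

## Known limitations

* The 58-feature catalogue follows standard formulas; exact numeric parity
  with the commercial tool used in the original study is impossible (its
  formulas are unpublished) and out of scope.
* The published Rad-score's coefficients are tied to that tool's feature
  scales; the shipped signature is a worked example and serialization
  reference, not a transferable classifier.
* Box-counting dimension at clinical VOI sizes has strong finite-scale
  bias (see above); it is comparable across masks of similar size, not an
  absolute dimension estimate.
* The phantom cohort plants one effect mechanism (spatial homogeneity);
  real radiomic signals are confounded with size, stage, acquisition and
  segmentation in ways the generator deliberately excludes.
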