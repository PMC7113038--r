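# radpdl1

CT-radiomics pipeline for predicting PD-L1 expression (tumor proportion
score ≥ 50%) in advanced lung adenocarcinoma — a tested, reusable R
reimplementation of a published single-center analysis, exercised end to
end on synthetic 3-D tumor phantoms because the original patient cohort is
private.

## Who it is for

Radiology/oncology researchers who want to (a) compute a standard 58-feature
radiomic panel from segmented CT volumes, (b) reproduce the three-step
feature-selection methodology (interobserver-ICC filter → univariate t-test
screen → repeated-cross-validation LASSO) that yields a **Rad-score**, and
(c) quantify what a radiomic signature adds to clinical covariates using
DeLong tests and bootstrap optimism-corrected c-indices — or who want a
fully synthetic, self-contained testbed for any of those pieces.

## The model in brief

For each segmented tumor (volume of interest, VOI) the package computes 58
features: 15 histogram, 2 gradient, 13 gray-level co-occurrence (GLCM), 13
gray-level run-length (GLRLM), 3 second-moment invariants, 11 shape, and a
box-counting fractal dimension. Selection proceeds in three steps:

1. keep features with two-reader ICC(2,1) > 0.75;
2. keep features separating PD-L1 groups at *p* < 0.05 (pooled t-test);
3. L1-penalized logistic regression, with the penalty λ chosen to maximize
   the mean AUC over 100 repeats of stratified 3-fold cross-validation.

The Rad-score is the raw-scale linear predictor of the final LASSO fit,

```
Rad-score = β₀ + Σ βf · feature_f ,
```

dichotomized at the Youden-optimal cutoff of its training ROC curve
(positive if strictly greater). Two nested logistic models — Model 1:
dichotomized age, sex, smoking, EGFR; Model 2: the same plus the
dichotomized Rad-score — are compared by the paired DeLong test and by
bootstrap (1000 resamples) optimism-corrected c-indices.

The frozen published four-feature signature
(`Texture_GLCM_ASM`, `Texture_GLRLM_RV`, `Texture_GLRLM_RE`,
`Texture_GLRLM_SRHGE`, intercept −1.59423, cutoff −0.715) ships as a JSON
fixture; `published_signature()` loads it.

## Worked example

```r
library(radpdl1)

# a synthetic cohort at the study conditions: 153 subjects, 53/153 positive
cfg <- pipeline_config(cohort = cohort_config(n_subjects = 153, seed = 1),
                       repeats = 100, B = 1000, seed = 1)
res <- run_pipeline(cfg)
summary(res$fit)
```

```
Three-step radiomic feature selection
Step 1 (reliability, ICC > 0.75): 42 features retained
Step 2 (t-test, p < 0.05): 9 features retained
<selection_report>
  9 candidate features; lambda grid of 100 values
  3-fold CV x 100 repeats: best mean AUC 0.845 at lambda ...
  ...
Rad-score: mean 0.679 (positives) vs -2.257 (negatives)
Training ROC: AUC 0.899, Youden cutoff -1.5736, sens 95.9%, spec 69.2%
```

42 of 58 features survive the emulated second reader (median ICC 0.88), 9
separate the groups univariately, and the LASSO keeps a handful of
homogeneity-type texture features. The Rad-score separates the planted
phenotype (smoother tumors are "PD-L1-positive" by construction), and

```r
print(res$comparison)
#> DeLong comparison: delta c = 0.293, P < 0.001
#> Bootstrap (B = 1000): corrected c 0.494 vs 0.823; delta c 95% CI 0.186-0.331
```

shows the radiomic model beating the (null-by-construction) clinical model,
the qualitative finding the methodology is designed to detect. Applying the
shipped published signature to any feature table:

```r
ft <- extract_cohort_features(list(generate_phantom(phantom_spec(), 1, 7)))
score_feature_table(ft)[, c("rad_score", "rad_score_positive")]
```

A thin command-line wrapper over the same pipeline lives in
`inst/scripts/radpdl1-pipeline.R`.

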