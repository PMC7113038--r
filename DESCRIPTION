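Package: radpdl1
Title: CT Radiomics Pipeline for Predicting PD-L1 Expression in Lung
    Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements, as a tested and reusable pipeline, a CT-radiomics
    analysis for predicting PD-L1 positivity (tumor proportion score >= 50%)
    in advanced lung adenocarcinoma. Provides a 58-feature radiomic engine
    (histogram, gradient, gray-level co-occurrence and run-length texture,
    moment invariants, shape, fractal dimension) over segmented 3-D volumes,
    interobserver ICC reliability filtering, a three-step feature selection
    ending in a cross-validated LASSO-derived radiomic score (Rad-score),
    Youden-index cutoff analysis, and comparison of clinical versus
    clinical-plus-radiomic logistic models with DeLong tests and bootstrap
    optimism-corrected c-indices. Because the original patient cohort is
    private, the package ships a synthetic 3-D tumor phantom generator that
    reproduces the statistical structure the analysis assumes, so every stage
    is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
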