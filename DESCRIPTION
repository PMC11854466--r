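Package: morphorep
Title: Reproducibility Scoring and Group Discrimination for Brain Morphometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for comparing brain-morphometric and cognitive
    features between irritable bowel syndrome (IBS) patients and healthy
    controls, and for quantifying how well such findings replicate across
    cohorts and processing pipelines. Provides Cohen's d with confidence
    intervals from summary statistics, Cliff's delta and Mann-Whitney tests,
    a composite per-region reproducibility score (directional consistency +
    confidence-interval overlap + minimum effect magnitude), multivariate
    normality screening (Mardia, Henze-Zirkler), a winsorized median-centered
    robust Mahalanobis distance with Hotelling-style inference, permutation
    tests for multivariate group differences, a classifier-agnostic
    stratified evaluation harness with a full confusion-matrix metric suite
    and permutation feature importance, and a synthetic two-group cohort
    generator emulating eTIV-normalized regional volumes, RBANS cognitive
    indices, and IBS symptom-severity scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
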