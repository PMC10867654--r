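Package: fatiguecast
Title: Wearable Digital Biomarkers and Additive Models for Momentary Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for modeling momentary (state) fatigue from
    arm-worn wearable biosignals in multiple sclerosis patients and healthy
    controls. Provides a seeded synthetic cohort generator with known ground
    truth, multi-horizon feature extraction (Poincare heart-rate-variability
    metrics from low-motion rest windows, electrodermal activity peaks,
    physical activity, daily-routine and weather features), per-participant
    normalization with zero imputation, shrinkage smoothing-spline additive
    models with a subsample backward-elimination variable-selection loop, and
    within-group, across-group, baseline, and ablation evaluation under
    leave-one-participant-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    mgcv,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
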