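Package: upliftRCT
Title: Uplift Modeling for Treatment-Benefit Stratification in Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies randomized-trial participants who benefit from an
    intensified treatment using one-model uplift modeling with class-variable
    transformation. Provides registration-order dataset splitting, leakage-safe
    preprocessing (missingness screening, mean/'not available' imputation,
    correlation pruning, robust interquartile-range scaling), a registry of
    probabilistic classifiers, Qini-curve construction with Qini-coefficient
    model selection and optimal cutoff choice, and cutoff-stratified survival
    validation (Kaplan-Meier, log-rank, Cox proportional hazards with
    treatment-by-stratum interaction and Schoenfeld diagnostics). A seeded
    synthetic two-arm trial generator with known covariate-dependent treatment
    benefit supports end-to-end validation against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    rpart,
    randomForest,
    xgboost,
    e1071,
    caret,
    MASS,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
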