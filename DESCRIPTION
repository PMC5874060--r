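Package: topsurv
Title: Trees of Predictors for Fixed-Horizon Survival Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalized survival risk prediction at fixed time horizons via
    trees of predictors: recursive discovery of predictive clusters in covariate
    space, where each split jointly selects the feature, threshold, base learner
    (Cox, linear, logistic) and training node to maximize validation AUC, and
    predictions average the models along each root-to-terminal path with
    non-negative weights fitted on validation data. Includes censoring-aware
    horizon labelling, cohort preprocessing (missingness filtering, one-vs-rest
    encoding, mean/mode imputation), evaluation metrics (tie-aware AUC,
    Harrell's concordance index, calibration with RMSE, sensitivity at fixed
    specificity), k-fold cross-validation, a synthetic heterogeneous-cohort
    generator with closed-form oracle risks, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: survival, stats, utils, jsonlite, yaml, pracma
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
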