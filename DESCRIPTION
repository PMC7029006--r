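Package: ntra
Title: Nonlinear Trimodal Regression Analysis of CT Radiodensity Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes mid-thigh CT radiodensitometric (Hounsfield unit)
    distributions into fat, loose-connective, and lean-muscle skew-Gaussian
    components (an 11-parameter soft-tissue profile), and provides the
    downstream cardiovascular-risk toolkit built on those parameters:
    synthetic cohort simulation, multivariate logistic regression with
    odds-ratio and deviance diagnostics, SMOTE class balancing, cross-validated
    tree-ensemble classification (random forests, AdaBoost, gradient boosting)
    with a tissue-grouped evaluation typology, and longitudinal incidence
    prediction for chronic heart failure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    randomForest,
    xgboost,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
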