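Package: caninecog
Title: Cognitive Test Batteries and Outcome Prediction for Working Dogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking individual differences in dog cognition to
    working-dog outcomes. Implements the two workflows used in applied
    canine-cognition screening programs: predictive modelling of
    assistance-dog graduation with an eight-family classifier ensemble,
    repeated stratified cross-validation, and quartile-stratified accuracy;
    and a directional consensus screen for detection-dog performance with a
    replication test on panels of standardized regression coefficients.
    Includes cohort data handling with exclusion accounting, Box-Cox and
    k-nearest-neighbour preprocessing, scoring of training logs and ordinal
    rating records, inter-rater reliability statistics, and a synthetic
    cohort generator with latent factor structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    randomForest,
    e1071,
    caret
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
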