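Package: cades
Title: Complication-Aware Dynamic Classifier Selection for Readmission Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting unplanned hospital readmission on tabular
    clinical cohorts using dynamic ensemble selection. Patient subgroups are
    characterized by interpretable conjunction rules over binary diagnosis
    (complication and comorbidity) indicators; a heterogeneous pool of base
    classifiers is trained on rule-defined data subsets; and a meta-classifier
    selects, per patient, the most competent classifiers using meta-features
    that include a class-balanced diagnosis-space region of competence.
    Includes a synthetic cirrhosis-like cohort generator with latent
    rule-defined subgroups, k-nearest-neighbor imputation, univariate variable
    screening (Mann-Whitney U, chi-square, Fisher exact), MELD scoring, and a
    stratified cross-validation harness with sensitivity-constrained
    thresholding and per-subgroup reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    randomForest,
    ranger,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
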