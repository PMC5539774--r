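Package: riskbn
Title: Bayesian-Network Risk Prediction for Tabular Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for building autonomous risk-prediction models from
    rectangular patient records with a binary outcome, in the style used for
    early detection of COPD exacerbations. Continuous predictors are
    discretized with the Fayyad-Irani minimum description length criterion,
    relevant attributes are selected by filters (gain ratio ranking with a
    half-maximum threshold, correlation-based feature selection) or wrappers
    (best-first and genetic search scored by cross-validated AUC), the
    classifier is a Bayesian network learned by the tree-augmented naive
    Bayes (TAN) or K2 algorithm with Cooper-Herskovits scoring, and models
    are evaluated by stratified k-fold cross-validation with ROC/AUC,
    minimum-distance cutoff selection, and gain-ratio-ordered incremental
    observation under partial evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    foreign,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
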