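Package: qsarscreen
Title: Ensemble QSAR Classification and Consensus Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A binary QSAR (quantitative structure-activity relationship)
    modelling and virtual-screening toolkit for kinase-inhibitor discovery.
    Curates activity records against an IC50 decision boundary, reduces
    molecular-descriptor tables by pairwise-correlation pruning followed by
    Boruta shadow-feature selection, trains a four-algorithm ensemble
    (support vector machine, random forest, gradient boosting, k-nearest
    neighbours), evaluates it with precision/recall/accuracy/F1, ROC-AUC,
    cumulative gain and outcome-stratified probability scores, checks model
    reliability with a PCA applicability domain and y-randomization, analyses
    166-bit structural-key fingerprints (Tanimoto similarity, per-class bit
    frequencies, differential bits), and screens compound libraries through a
    three-filter consensus funnel. Ships a synthetic-data generator so the
    whole pipeline is testable without external chemistry resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    rlang,
    randomForest,
    ranger,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
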