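Package: redpair
Title: Predicting Genetic Redundancy Between Paralogous Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labels mutant trios (two single mutants and the corresponding
    double mutant, each with an ordinal phenotype-severity class) under nine
    redundancy definitions of varying stringency plus a nonredundancy rule,
    engineers pair-level features from gene-level attribute tables
    (binary counts, categorical overlaps, continuous aggregations,
    square/log10/reciprocal transformations, quartile bins, and principal
    components), tests feature-class associations (Fisher's exact test,
    Wilcoxon rank-sum, Benjamini-Hochberg correction, effect sizes), and
    trains balanced down-sampling classifier ensembles (linear SVM, random
    forest, gradient boosting) with cross-validated hyperparameter search,
    random-forest or elastic-net feature selection, F1-maximizing decision
    thresholds, averaged ROC/PR curves, weight-based feature importances,
    cross-definition train/test protocols, and misprediction diagnostics
    (feature separation scores and PCA of mispredicted pairs). A synthetic
    benchmark generator with planted, tunable redundancy signal makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
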