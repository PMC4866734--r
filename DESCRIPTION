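Package: spatialTL
Title: Transfer Learning for Spatial Proteomics Protein Localisation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Transfer-learning classifiers for protein sub-cellular
    localisation that integrate a quantitative primary dataset (e.g. LOPIT
    density-gradient profiles) with a heterogeneous auxiliary dataset (e.g. a
    binary Gene Ontology Cellular Component term matrix) sharing the same
    proteins. Implements a class-weighted k-nearest-neighbour combiner with
    per-class primary/auxiliary weights optimised on a grid, and a two-kernel
    1-norm linear-programming support vector machine with one-vs-one
    multiclass decomposition, Morik class-imbalance weights, Platt sigmoid
    probabilities and pairwise coupling. Includes stratified benchmarking
    with macro F1 scores and Welch tests, ROC/AUC analysis, FDR-calibrated
    score thresholds for assigning unlabelled proteins, builders for
    auxiliary matrices from offline GO/HPA/STRING annotation files, and a
    synthetic paired-data generator with controllable per-class, per-source
    resolution.
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'accessors.R'
    'data-model.R'
    'aux-builders.R'
    'lp.R'
    'svm-tl.R'
    'evaluation.R'
    'knn-tl.R'
    'probabilities.R'
    'synthetic-data.R'
    'workflows.R'
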