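Package: mkconnectome
Title: Functional Connectome Graph Metrics and Multi-Kernel SVM Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional brain networks from regional time series
    (Pearson correlation with negative edges zeroed, proportional sparsity
    thresholding over a 0.02-0.5 grid), computes global and nodal binary-graph
    metrics with degree-preserving null-model normalisation and area-under-
    the-sparsity-curve aggregation, selects discriminative edges by two-sample
    t-tests with cross-validation consensus and discriminative nodal metrics
    by group-LASSO logistic regression, and discriminates two subject groups
    with a multi-kernel support vector machine under nested leave-one-out
    cross-validation, including DeLong comparison of correlated ROC curves.
    A synthetic-cohort generator with planted edge-weight and modularity
    differences provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
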