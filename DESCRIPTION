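Package: mgmdhafs
Title: Imbalance-Tolerant Drug-Target Classification with GMDH Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements mGMDH-AFS, an imbalance-tolerant classifier for
    predicting drug-target proteins from tabular biochemical and network
    topology features. The classifier is a self-organising GMDH (group
    method of data handling) network of pairwise nonlinear neurons whose
    parameters are fitted by particle swarm optimisation under a Matthews
    correlation coefficient fitness, preceded by I-RELIEF feature
    weighting, logistic encoding of categorical features and minority
    oversampling, with a final ROC-derived decision cutoff. Also provides
    the four reference classifiers it is benchmarked against (logistic
    regression, Poisson-link GLM, RBF-kernel SVM and RBF network with
    sequential forward selection), a full statistical validation harness
    (hold-out, k-fold, label-permutation test, Cochran's Q and McNemar
    post-hoc tests with Bonferroni correction), graph centrality feature
    computation for protein interaction networks, and a synthetic
    drug-target-like benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
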