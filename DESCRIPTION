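Package: cbmNet
Title: Network Propagation of Compound Targets and Anti-Cancer Likeness
    Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Propagates sparse compound-to-protein target sets over a scored
    human protein-protein interaction network using random walks with
    restarts, trains linear classifiers (maximum margin criterion and linear
    support vector machines) on the propagated genome-wide profiles to
    separate anti-cancer from non-anti-cancer drugs under stratified nested
    cross-validation, and scores arbitrary compounds (for example food
    molecules) with an ensemble anti-cancer likeness probability. Includes
    gene-importance scoring, per-food aggregation of cancer-beating molecule
    counts with correlation structure, a fully synthetic planted-module data
    generator for benchmarking, and a command-line pipeline wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Classification, SystemsBiology
RoxygenNote: 7.3.3
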