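Package: microGAT
Title: Graph Attention Networks over Microbial Co-Expression Networks for
    Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts a binary disease phenotype (atopic dermatitis) from
    genus-level gut-microbiome abundance profiles. Builds a compositional
    (CLR/COAT-based) co-expression network with subsample stability
    selection, induces sample-specific subgraphs over non-zero genera,
    trains a multi-head GATv2 graph attention classifier with an
    attention-based readout, and interprets predictions through
    CLR-normalized per-genus attention scores and randomized in-silico
    taxon-removal interventions. Includes a zero-inflated logistic-normal
    simulator with planted co-abundance blocks and planted discriminative
    genera so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
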