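Package: tfnet
Title: Consensus Transcription Factor Association Networks from
    Multi-Sample ChIP-Seq Binding Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds binary multi-sample transcription factor (TF) binding
    matrices from ChIP-seq peak files, estimates direct (conditional)
    dependence between samples with four independent algorithms (shrinkage
    partial correlation, graphical lasso, stability-selection regression
    and Bayesian-network structure learning), combines them into a
    consensus TF association network, analyses its topology, and
    benchmarks predicted TF pairs against a protein-protein-interaction
    gold standard.  Includes a planted-graph synthetic data generator so
    the whole pipeline can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    igraph,
    IRanges,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
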