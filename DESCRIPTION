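Package: dynfnc
Title: Static and Dynamic Functional Network Connectivity, Brain-State and
    Multilayer Network Switching Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional network
    connectivity downstream of group ICA. Computes per-subject static
    Fisher-z connectivity matrices, tapered sliding-window dynamic
    connectivity, k-means brain-state decomposition with temporal metrics
    (fraction time, mean dwell time, transitions), connectivity variability,
    windowed graph-efficiency flexibility over sparsity thresholds,
    multilayer-modularity community detection with an ordinal Louvain
    optimizer and per-node network switching rates, and a GLM /
    Benjamini-Hochberg / partial-correlation inferential layer with
    covariate adjustment. Includes a synthetic-cohort generator with
    Markov-switching covariance states and planted-partition layered
    networks so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
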