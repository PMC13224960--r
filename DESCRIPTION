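Package: omicnet
Title: Correlation-Based Network Construction and Analysis for Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalable construction and analysis of correlation-based
    association networks from high-dimensional feature-by-sample omics
    tables. Provides vectorized all-pairs Pearson and Spearman correlation
    with analytic t-distribution p-values and multiple-testing correction,
    random-matrix-theory (RMT) selection of the correlation threshold via
    the eigenvalue nearest-neighbour spacing distribution, module detection
    with fast greedy modularity optimization, Zi-Pi topological role
    classification, multi-omics (e.g. exposome-transcriptome) network
    assembly, a family of grouped and polygon-constrained layout
    algorithms, a 17-metric topology report, natural-connectivity
    robustness curves under random and targeted node removal, and readers
    and writers for GraphML, Pajek and edge-list formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
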