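Package: fcpyramid
Title: Pyramid (Multi-Scale) Representation of Resting-State Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses resting-state functional brain networks at five
    hierarchical parcellation scales: node time-course extraction against a
    multi-granularity gray-matter atlas (84/58/16/6/4 nodes), Pearson
    connectivity, proportional-threshold binarization, binary graph metrics
    (clustering coefficient, global and local efficiency, betweenness
    centrality), ALFF spectral features, node-wise group statistics with
    Benjamini-Hochberg FDR control, and multi-scale feature classification with
    a linear support vector machine under stratified cross-validation. Includes
    a synthetic BOLD cohort generator with hierarchical modular covariance and
    configurable group effects so the full pipeline is testable without
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
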