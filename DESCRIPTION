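Package: reservenet
Title: Graph-Based Connectivity of Protected-Area Networks Under Range
    Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses how well a system of protected sites stays connected
    for a dispersal-limited species, now and under a future habitat-suitability
    scenario. Builds dispersal-threshold graphs over site centroids, computes
    classical topology metrics (components, articulation points, betweenness,
    clustering, degree-distribution fit), habitat-weighted connectivity
    indices (probability-of-connectivity numerator, Equivalent Connected
    Area, Generalized Betweenness Centrality) under a negative-exponential
    dispersal kernel, and compares current versus future networks (dA, dECA,
    lost-versus-retained node properties) with subset-resampling permutation
    tests, Mann-Whitney U and Spearman rank correlation. Includes a synthetic
    reserve-network generator with clustered site placement, log-normal site
    areas and a degree-biased loss process for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
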