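Package: netrewire
Title: Degree-Preserving Targeted Rewiring of Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exploring how structural properties of social
    networks constrain one another. Builds random starting networks from
    degree sequences with the configuration model, then applies three
    separate degree-preserving rewiring algorithms that respectively
    increase degree assortativity, increase the mean local clustering
    coefficient, or decrease the mean geodesic distance, while tracking
    a panel of structural properties (centrality means and Gini
    coefficients, clustering, assortativity, geodesics) along each
    rewiring trajectory. Includes synthetic degree-sequence generators
    calibrated by Gini coefficient, an experiment orchestrator, and
    property-pair trajectory plots.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
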