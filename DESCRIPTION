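Package: riverweb
Title: Co-Occurrence Network Analysis of Riverine Bacteria and Archaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds correlation-based co-occurrence networks from OTU
    relative-abundance tables (prevalence filtering, tie-corrected Spearman
    correlations, Benjamini-Hochberg control), compares them against
    Erdos-Renyi null ensembles (small-world coefficient, degree-distribution
    model fits), quantifies intra- and inter-phylum co-existence with
    observed-versus-random incidence ratios, identifies keystone taxa from
    degree and betweenness centrality, computes network-level topological
    features on whole networks and per-sample subnetworks, and relates
    network structure to geography and environmental gradients with Mantel
    distance-decay tests and distance-based redundancy analysis. A synthetic
    community generator with planted module structure and spatially
    autocorrelated environmental covariates supports end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    vegan,
    geosphere,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
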