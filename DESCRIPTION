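Package: phylocomm
Title: Phylogenetically Informed Community Metabolic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges genome-scale metabolic models (GEMs) of phylogenetically
    related taxa into pooled higher-rank models with coefficient-averaged
    biomass reactions, builds abundance-weighted community models, and
    simulates community growth by cooperative-tradeoff or summed-growth
    optimisation. Includes flux balance and flux variability analysis on a
    built-in exact simplex solver, Jaccard reaction-set redundancy metrics,
    taxon-knockout interaction screens, blocked-metabolite interaction
    detection, Gaussian-noise sensitivity analysis of abundance inputs,
    Williams' test for dependent correlations, and seeded synthetic-data
    generators (toy GEMs, related model families, multi-sample cohorts) so
    the full pipeline is testable without external model databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
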