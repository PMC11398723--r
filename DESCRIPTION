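Package: ednet
Title: Multi-Echo fMRI Connectivity and Extended Default Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for multi-echo resting-state fMRI network
    analysis: simulation of multi-echo cohorts with planted network structure,
    TSNR-optimal echo combination, TE-dependence (ME-ICA style) denoising with
    kappa/rho component classification, degrees-of-freedom-adjusted Fisher-z
    functional connectivity from BOLD component coefficients (MEFC), Louvain
    modularity and map-equation (Infomap-style) community detection,
    eta-squared similarity with Ward agglomerative clustering of limbic
    connectivity profiles, and mass-univariate connectivity maps with
    Bonferroni and top-fraction thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
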