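Package: phylodd
Title: Phylogenetic Neighborhood Density Dependence in Seedling Survival
Version: 0.1.0
Authors@R: person("Plot", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for neighborhood analyses of seedling survival in
    stem-mapped forest dynamics plots. Computes focal-individual
    phylogenetic neighborhood indices (TOTPd, AVEPd, MINPd) and their
    standardized effect sizes (APd', NTPd') against taxa-shuffle null
    models, conspecific density covariates, and topographic habitat
    variables reduced by PCA; fits binomial mixed models of seedling
    survival with quadrat and species random intercepts; and scans model
    support (AIC, conditional R-squared) across phylogenetic indices,
    temporal scales and spatial scales. Includes a synthetic plot
    generator with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
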