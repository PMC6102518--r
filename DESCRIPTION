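Package: phyloturn
Title: Phylogenetic Community Structure, Turnover and Speciation-Scenario
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-phylogenetics pipeline for inferring dominant
    speciation modes from spatial patterns of phylogenetic turnover.
    Provides megatree grafting of family/genus/species taxon lists,
    bladj-style node-age calibration with random polytomy resolution,
    alpha (MPD, MNTD) and beta (betaMPD, betaMNTD) phylogenetic metrics
    with permutation-null standardized effect sizes (betaNRI, betaNTI),
    Jaccard similarity, simple and partial Mantel tests, AICc all-subsets
    model selection, detection of spatial aggregations from
    significantly-low-turnover community pairs, and a ground-truth
    simulator of allopatric versus sympatric speciation on a landscape
    with dispersal limitation and climate gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    geosphere,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
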