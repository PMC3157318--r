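Package: cryptdrift
Title: Agent-Based Simulation of Colon Crypt Stem-Cell Dynamics and APC
    Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lattice agent-based model of a colonic crypt: cell-cycle
    progression, mitotic-pressure migration and luminal shedding of
    epithelial cells, stochastic symmetric/asymmetric stem-cell division
    with homeostatic feedback on the differentiation probability, and a
    two-allele APC mutation layer.  Provides replicate orchestration for
    studying niche succession (monoclonal conversion), fixation of mutant
    stem-cell lineages, and waiting times to the second APC hit, plus a
    reduced stem-compartment birth-death simulator used as an independent
    cross-check of the lattice model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
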