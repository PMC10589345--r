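Package: enemyfix
Title: Mutant Fixation in Host Populations Attacked by a Natural Enemy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation and analysis of mutant fixation in
    spatially structured host populations that are attacked by a natural
    enemy (an SI-type pathogen) which infects wild-type and mutant hosts
    equally. Provides a 2D lattice agent-based host-pathogen model, a
    Gillespie-type deme (metapopulation) model with spatial or non-spatial
    migration, and a coarse-grained patch-competition approximation, together
    with the fixation-trial protocol (burn-in to quasi-equilibrium,
    equilibrium-triggered mutant introduction, absorption bookkeeping),
    Moran-process reference formulas, and estimation statistics for fixation
    probabilities and conditional fixation times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    deSolve,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
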