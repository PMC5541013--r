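Package: agevoter
Title: Ageing Voter Model on Partially Coupled Two-Layer Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulator for the binary-state voter model with
    node ageing (endogenous update, activation probability b/tau) and the
    standard random asynchronous update (RAU) on two-layer networks in
    which a fraction q of nodes is shared between layers. Generates
    complete-graph, periodic-lattice and configuration-model layers,
    couples them with random or degree-ranked pairings, runs seeded
    ensembles with a compiled update engine, and computes the observables
    of coarsening and dynamical trapping: active-link density, layer
    magnetization, mean persistence times, inter-event time distributions,
    power-law tail exponents, trapped-fraction curves and the multiplexity
    threshold q*. Closed-form activation probabilities and trapped-state
    plateau levels are provided for direct evaluation and as test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
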