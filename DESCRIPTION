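Package: chaosmorph
Title: Pattern Generation by Chaotic and Stochastic Morphogenesis Models
Version: 0.1.0
Authors@R:
    person("chaosmorph", "maintainers", email = "chaosmorph@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for pattern-generation mechanisms that combine
    Turing-type reaction-diffusion dynamics with Wolpert-style positional
    information. Integrates gradient-forced two-component reaction-diffusion
    systems on a periodic strip, reduces them by Galerkin projection onto
    localized segment bases whose amplitude dynamics can be calibrated to
    realize prescribed vector fields (including the chaotic Roessler system),
    enumerates coexisting local attractors of weakly coupled segment groups,
    models staged morphogenesis as absorbing Markov chains with exact
    hitting-time oracles, and converts chaotic or stochastic trajectories into
    discrete cellular differentiation programs through a morphogenetic
    operator over partitions of morphogen space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
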