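Package: jrnet
Title: Stochastic Jansen-Rit Cortical Column Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of networks of Jansen-Rit neural mass
    models driven by Ornstein-Uhlenbeck background noise and low-frequency
    periodic or composed multi-sine signals. Provides a stochastic Heun
    integrator for the coupled column/noise system, deterministic bifurcation
    analysis of the single column (equilibria, Hopf localization, attractor
    classification, the spiky/alpha coexistence window), Welch power spectral
    density estimation with band powers and relative-change maps, and
    configured experiment pipelines studying cross-frequency power transfer
    into the alpha band.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
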