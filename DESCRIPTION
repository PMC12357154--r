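Package: planktonchaos
Title: Chaos Detection in Temperature-Forced Plankton Food-Web Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced multi-plankton-functional-type food web
    driven by seasonal and stochastic (Ornstein-Uhlenbeck) water-temperature
    forcing with Q10 metabolic regulation, and identifies the resulting
    dynamical regime (extinct, stationary, periodic, chaotic) by three
    complementary approaches: indicator thresholds (coefficient of
    variation, frequency spectrum, Wolf-algorithm Lyapunov exponents),
    bifurcation diagrams built from trajectory envelope extrema, and the
    noise-robust multiscale complexity-entropy causality plane based on
    Bandt-Pompe ordinal patterns, permutation entropy and Jensen-Shannon
    statistical complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
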