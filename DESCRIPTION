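Package: critpoise
Title: Dynamical Criticality Models and Critical Mode Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulators and estimators for self-poised dynamical
    criticality in neural-network-like systems. Provides the forced Hopf
    normal form with its four critical signatures (amplification, sharp
    tuning, 1/3-power compression, mistuned oscillation), an anti-Hebbian
    plasticity model whose synaptic eigenvalues self-organize onto the
    imaginary axis, critically coupled map lattices built from
    antisymmetric couplings and their orthogonal exposure operators,
    spatiotemporal spectral-entropy phase diagrams, and windowed AR(1)
    critical mode analysis of multichannel time series with surrogate
    controls and condition-contrast permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
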