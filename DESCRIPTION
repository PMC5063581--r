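Package: popspectra
Title: Mean-Field Prediction of Population Rate Spectra in Spiking
    Circuit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts population firing-rate power spectra of
    multi-population networks of leaky integrate-and-fire neurons by a
    combination of diffusion-approximation mean-field theory and linear
    response theory. Computes self-consistent stationary rates, colored-noise
    population transfer functions, the delay-averaged effective connectivity
    matrix and its per-frequency eigenmode decomposition, and an eigenvalue
    sensitivity measure that maps every anatomical connection to its
    influence on the amplitude and frequency of oscillation peaks.
    Includes Laplace-domain stability classification of the dynamical
    modes, extraction of minimal oscillation-generating sub-circuits, a
    stochastic linear rate-model simulator used as a numerical cross-check,
    and a bundled multi-layer cortical microcircuit parameter set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
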