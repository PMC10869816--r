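Package: cordichr
Title: Multiplier-Free CORDIC Approximation of the Hindmarsh-Rose Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bit-exact simulation of a fixed-point, multiplier-free
    approximation of the Hindmarsh-Rose spiking neuron in which the quadratic
    and cubic nonlinearities are evaluated by linear-mode rotation CORDIC
    blocks built only from shifts and additions. Provides the floating-point
    reference model, inter-spike-interval bifurcation and chaos analysis,
    nullcline and equilibrium comparison, time-domain error metrics, a random
    excitatory/inhibitory network simulator, spike-frequency Boolean gates,
    and cellular-logic spiking image filters for edge detection,
    magnification and noise removal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
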