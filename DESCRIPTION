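Package: cvrate
Title: Complex-Valued Firing-Rate Models of Spiking Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing populations of integrate-and-fire neurons to
    low-dimensional firing-rate dynamics. Implements the linear (leaky),
    quadratic and exponential integrate-and-fire models driven by white-noise
    input; Monte-Carlo population simulators; steady-state, first-passage and
    spectral solvers for the associated Fokker-Planck equation (threshold
    integration for the LIF/EIF, a Fourier expansion of the theta-model for
    the QIF); the classic single-time-constant rate model and a complex-valued
    rate model whose decay and oscillation rates follow the dominant nonzero
    Fokker-Planck eigenvalue; linear-response (gain and phase) calculators;
    and excitatory-inhibitory network analysis, including sparse spiking
    network simulation, two-unit complex-rate network integration, fixed
    points, Jacobian stability and synaptic-weight phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    readr
Config/testthat/edition: 3
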