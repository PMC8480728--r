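Package: whiskstdp
Title: Spike-Timing-Dependent Plasticity and the Distribution of Whisking
    Phase Tuning in a Feed-Forward Thalamocortical Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models rhythmically driven thalamocortical feed-forward synapses
    under spike-timing-dependent plasticity (STDP). Provides the mean-field
    (slow-learning) dynamics of the synaptic weight profile, an event-level
    spiking simulator used as a validation oracle, a self-consistent
    fixed-point solver, circular (von Mises) statistics for the drifting
    preferred phase of the downstream neuron, and a plasticity-free pooling
    baseline. Results are returned as tibbles with broom-style tidiers and
    ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
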