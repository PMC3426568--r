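Package: somnox
Title: Heterogeneous Orexin-Neuron Model of Homeostatic Sleep-Wake Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a conductance-based network of orexin (hypocretin)
    neurons reciprocally coupled to a glutamate interneuron, in which the
    homeostatic sleep drive is implemented as activity-dependent depletion
    and recovery of orexin availability and the circadian drive as a
    periodic rectangular current pulse. Provides a stochastic Heun
    integrator with additive membrane-current noise, quenched diversity of
    synaptic half-activation thresholds drawn from a bell-shaped density, a
    sleep-wake quality coefficient computed from spike trains, and sweep
    drivers that reproduce stochastic-resonance and diversity-induced
    resonance experiments from a sub-threshold double-periodic reference
    state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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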