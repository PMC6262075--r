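Package: switchdyn
Title: Dynamics of a Bistable Molecular Switch Under Calcium Forcing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of a reduced bistable molecular-switch
    model of CaMKII-like kinase activation driven by calcium input. Provides
    the nondimensionalized Hill-activation drift and potential, saddle-node
    bifurcation and hysteresis analysis, generators for Poisson pulse trains,
    alpha-kernel and exponential-decay calcium transients, sinusoids and
    Ornstein-Uhlenbeck noise, a compiled Runge-Kutta integrator with a
    stochastic-Euler noise channel, uniqueness/convergence diagnostics based
    on a Gronwall bound, stochastic-resonance characterization via spectral
    gain sweeps, and long-timescale autonomous-activation protocols that
    reproduce classic frequency-decoding experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
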