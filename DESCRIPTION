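Package: opsin22
Title: Double Two-State Opsin Photocurrent Models with Autonomous Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and autonomous parameter inference for light-gated ion
    channel (opsin) photocurrents using a double two-state gating model: an open
    fraction and a dark-adaptation conductance factor, each relaxing to
    irradiance- and voltage-dependent equilibria. Provides the closed-form
    voltage-clamp solution and an ODE route, extraction of the seven standard
    photocurrent features (peak, plateau, ratio, activation, inactivation,
    deactivation and recovery time constants), a staged fitting procedure
    (multistart least squares followed by bounded particle-swarm refinement),
    goodness-of-fit metrics, a conductance-based regular-spiking cortical neuron
    driven by the opsin current, and strength-duration analysis (temporal
    average current, Hill-Lapicque rheobase and chronaxie, and an empirical
    irradiance mapping). Ships parameter fixtures for channelrhodopsin-2(H134R)
    and a MerMAID anion channelrhodopsin, and a synthetic voltage-clamp data
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
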