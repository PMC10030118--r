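Package: tectalnp
Title: Recurrent Linear-Nonlinear-Poisson Network Dynamics of the Larval Zebrafish Tectum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses ongoing and visually evoked population
    activity in the larval zebrafish optic tectum with a minimal stochastic
    spiking network model. A linear-nonlinear-Poisson (LNP) simulator with
    fast, short-range recurrent excitation and slow, long-range
    activity-dependent suppression generates intermittent localised bursting;
    companion modules detect bursts by density clustering, characterise
    pairwise correlation structure, calibrate the seven global model
    parameters by elitist evolutionary multi-objective optimisation with
    pattern-search refinement, estimate per-neuron excitability (linear
    drive) from recent spiking history, and analyse receptive fields,
    post-stimulus suppression and stimulus-specific adaptation under
    oddball-style protocols. A synthetic-data module generates all inputs so
    every analysis runs end-to-end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    methods,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
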