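Package: dominonet
Title: Domino-Like Seizure-Onset Patterns on Bistable Node Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterisation and mechanistic modelling of domino-like
    seizure-onset patterns in multichannel electrophysiology.  Provides
    threshold-based onset detection for EEG-like and entorhinal-cortex
    LFP-like recordings, classification of onset patterns into fast-,
    slow- and multi-domino groups by total recruitment time and maximum
    lag, estimation of functional coupling (nonlinear regression
    association index) and node excitability (signal energy) from data,
    fast stochastic simulation of networks of bistable Hopf-normal-form
    nodes with escape-time extraction, and quantitative model-data
    comparison including gradient parameter sweeps and severed-chain
    experiments.  Synthetic recordings with prescribed onset geometry
    support validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
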