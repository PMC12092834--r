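Package: measbi
Title: Simulation-Based Inference of Biophysical Mechanisms from
    Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers biophysical mechanisms underlying the activity of
    cultured neuronal networks recorded on multi-electrode arrays (MEAs).
    Provides a stochastic Hodgkin-Huxley network simulator with AMPA/NMDA
    synapses, Tsodyks-Markram short-term depression and asynchronous
    release; extracellular-signal pre-processing and threshold spike
    detection; a thirteen-feature MEA summary-statistic extractor with
    network-burst and burst-fragment detection; an amortized neural
    posterior estimator (conditional masked autoregressive flow) over ten
    model parameters; and the posterior-analysis and statistics layer used
    to compare experimental conditions per network and per batch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    signal,
    jsonlite,
    stats,
    utils,
    MASS,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
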