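Package: alphaloop
Title: Closed-Loop Alpha-Band Feedback Stimulation: Circuit Model, Simulator
    and LFP Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models an analog multiple-feedback (MFB) band-pass filter used for
    phase-locked transcranial alternating-current stimulation of cortical alpha
    (8-15 Hz) oscillations, simulates the closed feedback loop acting on a
    stochastic alpha oscillator, generates synthetic multi-array local field
    potential sessions with known injected band-power effects, and implements
    the complete offline analysis pipeline: epoching around stimulation events,
    Morlet wavelet time-frequency power, median-based single-trial baseline
    normalization to decibels, band summaries in a post-stimulation window,
    bootstrap and permutation inference with Benjamini-Hochberg false-discovery
    control, and the decomposition of power into phase-locked and
    non-phase-locked streams.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
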