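Package: somnirl
Title: Sleep-State Analysis from EEG Microstates, Lempel-Ziv Complexity,
    and Attention-Based Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying wake and sleep states from multichannel
    scalp EEG. Implements deterministic signal conditioning (zero-phase
    Butterworth band-pass, notch, re-referencing, epoching), Welch power
    spectral density and band power, EEG microstate analysis (global field
    power, GFP-peak topography extraction, polarity-invariant modified
    k-means with global explained variance model selection, backfitting,
    and temporal parameters), Lempel-Ziv complexity of the Hilbert analytic
    amplitude with median binarization, non-parametric statistics
    (Kolmogorov-Smirnov normality, exact and approximate Mann-Whitney U
    with eta-squared effect sizes), and an attention-glimpse CNN+GRU agent
    trained by policy-gradient reinforcement learning with a learned value
    baseline. A seeded synthetic EEG generator with ground-truth microstate
    sequences, state-dependent band power, and tunable signal complexity
    makes every stage testable without access to clinical recordings.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
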