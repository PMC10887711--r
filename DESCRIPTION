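Package: tpdcnet
Title: Time-Resolved Directed Connectivity for Oscillatory EEG Source Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for directed network inference
    from multivariate oscillatory time series, aimed at EEG source signals in
    the mu (8-12 Hz) and low-beta (13-20 Hz) bands. Provides a synthetic-data
    generator for ground-truth directed source networks (stable multivariate
    autoregressive models with band-limited oscillatory poles), forward
    projection to sensors, and behavioural sessions under the equal-variance
    signal-detection model; preprocessing (average re-referencing, block
    trimming, epoching, artifact rejection) and the event-related
    desynchronization index; DICS-style frequency-domain beamforming with
    coherent-source power and coherence maps and pooled source signals;
    time-resolved partial directed coherence estimated by a dual extended
    Kalman filter, with window-shuffling surrogate thresholds and a
    time-reversal validation test; rank-based group statistics, d-prime
    scoring, brain-behaviour correlation; and polynomial-kernel SVM group
    classification with repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
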