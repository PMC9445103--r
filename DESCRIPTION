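Package: prioEEG
Title: Simulation and Analysis of Task-Prioritization EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing electroencephalography (EEG)
    experiments in which one of two nested tasks is cued as more important on
    each trial. Provides a synthetic-data generator for the dual-task
    retro-cue paradigm (balanced trial schedules, behavioural outcomes,
    feedback scores, and epoched multichannel EEG with planted oscillatory
    effects), complex Morlet wavelet time-frequency decomposition with
    full-width-at-half-maximum parameterisation and decibel baseline
    normalisation, nonparametric cluster-based permutation tests over
    electrode x frequency x time grids and over time courses, hemispheric
    alpha-power lateralization indices relative to retro-cue direction,
    time-resolved decoding with trial-group-averaged linear support vector
    machines, and follow-up inference (t tests, Cohen's d, adjusted partial
    eta squared, and Jeffreys-Zellner-Siow Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
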