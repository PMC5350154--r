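Package: betachoice
Title: Choice-Selective Beta-Band EEG Analysis for Vibrotactile Frequency Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-alternative forced-choice
    vibrotactile frequency comparison experiments with EEG. Implements a
    Bayesian observer model of perceived frequency differences (contraction
    bias, maximum-likelihood fitting, BIC-based Bayes factors), Morlet
    wavelet time-frequency transformation of response-locked epochs,
    subject-level factorial contrasts with group-level sign-flip
    cluster-based permutation testing and conjunction (minimum-statistic)
    inference, signal-detection and response-time behavioural statistics,
    and a seeded synthetic-data generator that produces trial tables and
    multichannel epoched EEG carrying the statistical structure the
    downstream analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
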