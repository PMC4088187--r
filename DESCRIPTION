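Package: smrphase
Title: Sensorimotor-Rhythm Band Power, Phase Locking and Phase-Pattern
    Dynamics for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("smrphase", "developers", email = "smrphase@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing sensorimotor-rhythm correlates of motor
    imagery between participant groups from multichannel EEG: common-average
    referencing, trial segmentation and amplitude-based artifact rejection,
    band-limited RMS band power with pre-cue baselining (event-related
    desynchronization), Hilbert-phase extraction and across-trial
    phase-locking values, phase-microstate dynamics via the Instantaneous
    Instability Index, global phase-synchronization episode segmentation,
    K-means labelling and discrete-emission hidden Markov models with
    leave-one-out group classification, plus stepwise-regression group
    statistics.  Includes a deterministic synthetic-cohort generator with
    controllable desynchronization depth, inter-channel phase coupling and
    phase-pattern switching rates so that every stage of the pipeline can be
    validated without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
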