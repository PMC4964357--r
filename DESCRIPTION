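Package: fernpipe
Title: Simulation and Analysis of Feedback-Locked EEG in Monetary and
    Social Reward Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for feedback error-related negativity
    (fERN/FRN) studies in children: simulators for a two-deck child version
    of the Iowa Gambling Task and a rigged observed Prisoner's Dilemma Game,
    a synthetic high-density EEG generator with group-dependent
    feedback-locked components, standard ERP preprocessing (downsampling,
    zero-phase bandpass filtering, mastoid re-referencing, epoching,
    baseline correction, artifact rejection), bootstrap Monte Carlo
    waveform statistics with effect sizes, and depth-weighted L2
    minimum-norm source estimation on an analytic multi-shell spherical
    head model with anterior-cingulate ROI contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
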