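Package: pepkit
Title: Perturbation-Evoked Potential Analysis for Platform-Translation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of perturbation-evoked potentials (PEPs)
    recorded during support-surface translations: a 34-trial translation
    protocol with unpredictable catch trials, detection of perturbation
    onset from the platform accelerometer, zero-phase Butterworth band-pass
    and notch filtering of multi-channel EEG, extraction of 300 ms
    post-onset epochs with baseline detrending and z-correction,
    first-trial normalization, per-epoch root-mean-square and peak
    magnitude summaries, and split-plot (repeated-measures mixed) three-way
    ANOVA with Tukey HSD post-hoc tests and Cohen's d effect sizes.
    Includes a synthetic-cohort generator that simulates synchronized
    multi-rate EEG and platform-acceleration sessions with a configurable
    evoked-response effect structure, plus readers for EDF and BrainVision
    sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    rlang,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
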