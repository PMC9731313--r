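Package: mferp
Title: Multifeature Oddball ERP Simulation and Longitudinal Mixed-Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a pediatric multifeature
    auditory oddball (mismatch negativity) experiment. Generates constrained
    pseudorandom stimulus sequences, synthesizes ground-truthed multichannel
    EEG for a cochlear-implant vs normal-hearing cohort measured at two
    timepoints, preprocesses it (zero-phase filtering, downsampling, nose
    re-referencing, epoching, adaptive and fixed voltage rejection, baseline
    correction) with retention accounting, extracts per-sample median ERPs and
    frontocentral ROI difference waveforms, detects and quantifies the pMMR,
    MMN, P3a and LDN responses under an ordered time-window scheme with
    fallback rules, and runs the significance gates and staged linear mixed
    models for clinical group, age group, time and singing covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
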