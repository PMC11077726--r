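Package: gapassr
Title: Gap-in-Noise Auditory Steady-State Response and ERP Analysis for
    Mouse EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-channel (auditory and
    frontal cortex) mouse EEG experiments probing auditory temporal
    processing.  Constructs 40 Hz gap-in-noise auditory steady-state
    response (gap-ASSR) stimulus schedules and narrowband-noise ERP
    sessions, generates synthetic epidural EEG with configurable 1/f
    background noise, evoked P1/N1/P2 components and phase-jittered 40 Hz
    gap-evoked oscillations, and analyses recordings via epoching, baseline
    correction, detrending, complex Morlet wavelet inter-trial phase
    clustering (ITPC) grouped by gap width and modulation depth, ERP peak
    extraction, and a repeated-measures statistical battery (factorial and
    repeated-measures ANOVA with Mauchly sphericity tests,
    Greenhouse-Geisser correction, Tukey/Bonferroni/Sidak post hoc
    contrasts and residual diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    ggplot2,
    withr
Config/testthat/edition: 3
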