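Package: respiradar
Title: Contactless Respiration Monitoring with IR-UWB Radar and Skeleton Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for contactless monitoring of
    breathing in up to two subjects with impulse-radio ultra-wideband (IR-UWB)
    radars and a depth-camera skeleton tracker. Provides a scene and waveform
    simulator (five respiratory patterns: eupnea, Cheyne-Stokes, Kussmaul,
    apnea and non-stationary), radar-matrix preprocessing (resampling,
    background subtraction, truncated-SVD clutter removal), skeleton-based
    subject localization and motion detection, geometric multi-radar
    selection, range-bin respiratory-signal extraction, random-forest
    respiration-pattern classification with a morphological discriminator and
    signal quality index, peak-interval respiration-rate estimation, and a
    sliding-window stream orchestrator with a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    randomForest,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
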