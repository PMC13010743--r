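Package: gazescreen
Title: Task-Evoked Eye-Tracking Screening for Pediatric Unilateral Amblyopia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for screening unilateral amblyopia
    in children from task-evoked binocular eye tracking at 30 Hz. Provides a
    synthetic cohort generator for three oculomotor tasks (free visual search,
    orientation-dependent grating fixation, and two-dimensional sinusoidal smooth
    pursuit), the full preprocessing chain (cyclopean gaze construction, validity
    screening, gap interpolation, Savitzky-Golay smoothing), dispersion-based
    fixation segmentation (I-DT), saccade-like event and catch-up saccade
    detection, trial-level oculomotor feature extraction (scan-path transition
    entropy, orientation-referenced drift, convex-hull dispersion, pursuit gain),
    a calibrated Random Forest classifier evaluated under a leakage-resistant
    nested leave-one-subject-out protocol with isotonic probability calibration
    and Youden-J operating-point selection, and a statistical reporting layer
    (group comparisons with FDR control, Wilson intervals, subject-level
    bootstrap, calibration metrics, and prevalence-adjusted predictive values).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    ranger,
    glmnet,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
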