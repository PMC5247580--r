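Package: cardiogate
Title: Cardiac-Cycle-Gated Stimulus Presentation: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing cardiac-cycle-gated behavioural
    experiments, in which brief stimuli are timed to coincide with the systolic
    or diastolic phase of the cardiac cycle via online R-wave prediction.
    Provides a heart-rate-variability simulator (Gaussian AR(1) inter-beat
    intervals with optional respiratory modulation), online R-wave detection
    and next-beat prediction, a closed-loop gating simulator, a-posteriori
    phase recoding with exclusion accounting, signal-detection (d-prime,
    criterion) and process-dissociation (controlled/automatic) indices,
    fully within-subject 2x2x2 repeated-measures ANOVA with planned paired
    contrasts and Newman-Keuls correction, and a synthetic-cohort generator
    with configurable phase-dependent response bias for power and
    type-I-error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    generics,
    ggplot2,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
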