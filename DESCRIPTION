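Package: nbo
Title: Closed-Loop Neuroadaptive Bayesian Optimisation for Infant ERP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running and analysing closed-loop neuroadaptive Bayesian
    optimisation (NBO) experiments on infant event-related potentials. Implements
    block-wise real-time-style EEG preprocessing with artifact rejection and
    quality gating, extraction of the Nc mean-negativity target metric, a
    Gaussian-process surrogate with acquisition-based stimulus selection over a
    discrete face-morph stimulus space, per-subject session orchestration with
    burn-in, repetition and early-stopping rules, and the post-hoc outcome
    statistics (proportion tests, mixed repeated-measures ANOVA, linear and
    logistic regressions). A synthetic-EEG cohort simulator with controllable
    Nc tuning curves, pink-noise background and fussiness-driven attrition makes
    the entire loop testable without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
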