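Package: proteostate
Title: Longitudinal CSF Proteomics and State-Transition Modeling of ALS
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal cerebrospinal-fluid (CSF) proteomic
    biomarker discovery that separates fast-progressing from
    slow-progressing amyotrophic lateral sclerosis (ALS). Implements
    cross-sectional differential abundance testing (exact Mann-Whitney
    with Benjamini-Hochberg correction and fold-change filtering),
    repeated double cross-validation random-forest panel selection,
    logistic/ROC panel evaluation with bootstrap confidence intervals,
    random-slope mixed models for marker trajectories, nearest-neighbour
    mutual-information ranking, and an Ornstein-Uhlenbeck state-transition
    model of proteome variance over time, including diffusion-bridge
    backcasting to pre-symptomatic time. A seeded synthetic-cohort
    generator emulates the longitudinal data structure so that every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
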