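Package: hgfsocial
Title: Dual-Stream Hierarchical Gaussian Filter Models of Social and
    Non-Social Probabilistic Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, inversion and validation of trial-by-trial
    learning models for a probabilistic reward task in which a social cue
    (gaze) and a non-social cue (card colour) carry independent, volatile
    reward information.  Provides canonical task schedules, synthetic
    cohort generation, three-level binary hierarchical Gaussian filters
    run in parallel over the two information streams, Rescorla-Wagner and
    Sutton K1 comparison learners, response models that combine the two
    belief streams through a social weighting factor, subject-level MAP
    estimation with Laplace-approximated log model evidence,
    random-effects Bayesian model selection (exceedance and protected
    exceedance probabilities), parameter-recovery and posterior-predictive
    checks, and a model-agnostic lagged regression analysis of choice
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
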