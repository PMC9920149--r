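Package: gazeou
Title: Ornstein-Uhlenbeck Modelling of Gaze Dynamics for Behavioural Biometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based eye-movement biometrics. Segments raw gaze
    trajectories into fixations and saccades, models each event as a
    two-dimensional Ornstein-Uhlenbeck process pulled towards an attractor
    (the fixation centre or the saccade landing point), infers the drift
    and diffusion matrices of every event by Bayesian approximation
    (Laplace or mean-field variational), summarises the posteriors into a
    twelve-dimensional event descriptor, and identifies subjects with
    per-event-kind one-vs-rest support vector machines fused at the score
    level. Includes an exact composite (switching) Ornstein-Uhlenbeck
    simulator for synthetic multi-subject cohorts, cross-validated
    biometric evaluation (accuracy, F1, EER, AUC, confusion, cumulative
    match score) and intra/inter-subject correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
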