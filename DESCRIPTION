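Package: transdx
Title: Transdiagnostic Psychiatric Dimensions and Reinforcement Learning in
    Three-Armed Bandit Tasks
Version: 0.1.0
Authors@R:
    person("transdx", "developers", email = "transdx-dev@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for computational-psychiatry analyses of
    reward-seeking and loss-avoidance bandit behaviour. Provides drifting
    three-option probability schedules, eight reinforcement-learning models
    (Q-learning with value forgetting, choice-trace perseveration, asymmetric
    learning rates, and Pearce-Hall associability), per-participant maximum
    likelihood fitting, random-effects Bayesian model selection with exceedance
    probabilities, lagged reward/choice history regressions with
    false-discovery-rate control, polychoric-correlation factor analysis of
    ordinal symptom questionnaires (CNG factor-number test, promax rotation,
    Harman factor scores), dimension-versus-parameter statistics with
    leave-one-out cross-validated prediction and permutation tests, and a
    synthetic-cohort generator with planted ground truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
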