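Package: grlearn
Title: Generalized Reinforcement Learning for Hierarchical Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and subject-level maximum-likelihood modeling of a
    counterbalanced hierarchical reversal-learning task. Provides a seeded
    task generator with exact-count probabilistic reward schedules, a zoo of
    choice models (generalized reinforcement learning with state and action
    generalization, metastate-prediction-error and hidden Markov belief
    learners, dual-systems mixtures, and hysteresis/intercept/chance
    baselines), free-running and yoked agent simulation, Nelder-Mead
    maximum-likelihood fitting with AICc model comparison, learner and
    generalizer classification, model and parameter recovery, and the
    model-independent behavioral statistics used to validate the models
    (first-generalization accuracy, conditional repeat probabilities,
    psychometric choice and reaction-time regressions, posterior predictive
    checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
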