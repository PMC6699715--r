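Package: socialrl
Title: Social Reinforcement Learning in Private and Social Contexts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of instrumental learning in
    private and social contexts. Implements a three-condition probabilistic
    two-armed bandit task with a simulated demonstrator, a social
    reinforcement-learning model combining Q-learning with choice imitation
    and vicarious (observational) outcome learning, per-subject
    maximum-a-posteriori fitting with gamma/beta priors, random-effects
    Bayesian model selection with exceedance probabilities, parameter- and
    model-recovery diagnostics, a synthetic-cohort generator with
    questionnaire scores coupled to model parameters, and downstream
    correlation, meta-analytic and threshold-classification analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    metafor,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
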