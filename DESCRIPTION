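Package: decaytd
Title: Temporal-Difference Learning Simulators with Value Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for temporal-difference (TD) reinforcement learning
    models of the dopamine-striatum system in which learned values (or value
    weights) decay over time. Implements tabular TD with multiplicative
    value decay, linear-feature TD under punctate, sparse, dense, successor
    and predecessor state representations (including online learning of
    successor-representation features), an online value-RNN trained with
    random feedback, a hierarchical two-circuit model with conditioned
    reinforcement, and two distributional RL algorithms (integrated versus
    segregated reward-prediction errors) together with distribution- and
    mean-coding strength metrics. All experiments run on internally
    generated cue-delay-reward Pavlovian trial sequences and produce tidy
    per-time-step traces of values and TD reward-prediction errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
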