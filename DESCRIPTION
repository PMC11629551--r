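Package: twostepRL
Title: Hybrid Model-Based/Model-Free Reinforcement Learning for the
    Two-Step Markov Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of the two-step sequential decision
    ("two-step Markov") task. Provides a generative task environment with
    drifting Gaussian-random-walk reward probabilities, a seven-parameter
    hybrid model-free/model-based Q-learning agent, trial-wise likelihood
    evaluation with MAP and hierarchical Bayesian (MCMC) parameter
    estimation, automatic behavioural quality-control filters,
    stay-probability analysis of model-free and model-based choice
    signatures, salivary-cortisol stress-response preprocessing, and the
    group-level statistical layer (Welch and Mann-Whitney comparisons,
    MAD outlier trimming, normality screening, interaction regression of
    the model-based weight on group and cortisol increase, default
    Bayes-factor correlations, and power analysis), together with a
    calibrated synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
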