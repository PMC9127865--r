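Package: oppolearn
Title: Opposing-Learning and Context-Dependent Value-Learning Models for
    Instrumental Learning Tasks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of three-phase instrumental
    learning tasks with magnitude rewards under partial or complete feedback.
    Implements a family of trial-by-trial reinforcement-learning models --
    standard and forgetting Q-learning, reference-point, difference, hybrid
    regret/relief, experience-weighted attraction, sample-based episodic, a
    relative-asymmetric learner, and the Opposing Learning (OL) model in which
    the chosen prediction error updates chosen and unchosen values in opposite
    directions.  Provides a task simulator with adaptive learning-phase length,
    synthetic-cohort generation, maximum a posteriori fitting with softmax
    choice likelihoods, BIC/AIC and transfer-phase predictive likelihoods,
    random-effects Bayesian model selection (exceedance and protected
    exceedance probabilities), and parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
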