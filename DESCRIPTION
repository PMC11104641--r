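Package: sampleBDT
Title: Normative Use of Probability Density Information Derived from Samples
Version: 0.1.0
Authors@R:
    person("sampleBDT", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how decision makers use probability-density
    information derived from small Gaussian samples. Implements exact and
    quadrature-based region probabilities for bivariate Gaussian endpoint
    models, the linear-in-log-odds (LLO) probability-distortion model with
    maximum-likelihood fitting, additivity tests over disjoint intervals, a
    normative Bayesian-decision-theory set-point model with a uniform prior
    over the population variance and a chi-square-form likelihood,
    influence-function estimation via ridge regression with 10-fold
    cross-validation and the one-standard-error rule, Monte-Carlo normative
    influence, the Max-Point heuristic, AICc/BIC model comparison, reward
    scenario analyses, and synthetic-data generators emulating the
    interval-estimation and decision tasks with artificial observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
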