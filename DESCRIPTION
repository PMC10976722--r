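Package: evaluesim
Title: Monte Carlo Evaluation of the E-Value Under Unobserved Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how the E-value sensitivity
    statistic behaves when propensity-score methods amplify imbalance in
    unobserved confounders. Generates cohorts from a latent-utility treatment
    assignment and logistic cure model with a tunable correlation between the
    observed and unobserved confounders, estimates the treatment effect under
    five adjustment strategies (unadjusted, observed-confounder and
    full-information logistic regression, probit-based inverse probability of
    treatment weighting, and 1:1 greedy caliper propensity-score matching),
    and summarises covariate balance (standardized mean differences), common
    support, estimate bias, standardized risk ratios and E-values across
    replicates.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
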