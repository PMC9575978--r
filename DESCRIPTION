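Package: incentdce
Title: Discrete Choice Experiments for Financial-Incentive Smoking-Cessation Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for designing and analysing discrete choice experiments
    (DCEs) on financial-incentive smoking-cessation programs. Builds
    utility-neutral (null-prior) D-efficient paired choice designs by
    coordinate exchange, with level-balance, overlap and orthogonality
    diagnostics and a dominance-check set; simulates respondent cohorts
    under a panel random utility model with normally distributed individual
    coefficients, income interactions and an opt-out alternative-specific
    constant; applies the standard exclusion cascade (nontraders,
    dominance-check failures, universal opt-outs) and encodes cleaned data
    into a three-alternative long format with effects coding; estimates a
    panel mixed logit by maximum simulated likelihood with Halton draws;
    and computes post-estimation quantities, willingness to accept with
    Krinsky-Robb confidence intervals, predicted program uptake across
    incentive amounts, and the enrolment-indifference amount.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
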