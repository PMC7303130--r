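Package: dynpt
Title: Dynamic Prospect Theory Models of Sequential Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how previous outcomes reshape risky
    monetary choice. Implements the Prospect Theory Plus (PT+) valuation and
    softmax choice model with trial-by-trial additive updating of its four
    parameters (risk attitude, loss aversion, choice consistency, decision
    bias), a nine-model battery of random-intercept logistic regressions of
    binary choice on current options and lagged events (with log-likelihood
    ranking, likelihood-ratio and Wald tests), and hierarchical Bayesian
    estimation of the eight-parameter dynamic model by adaptive
    Metropolis-within-Gibbs MCMC with split-chain Rhat and effective-sample-
    size diagnostics. A synthetic-task module simulates the mixed
    gain-loss / gain-only gambling task so every stage is testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    lme4,
    jsonlite,
    readr,
    withr,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
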