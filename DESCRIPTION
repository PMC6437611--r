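Package: rdsize
Title: Population Size Estimation from Respondent-Driven Sampling Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian population size estimation for hidden populations
    sampled by respondent-driven sampling (RDS). Implements successive
    sampling population size estimation (SS-PSE) with joint imputation of
    participant visibility under a Conway-Maxwell-Poisson measurement-error
    model for self-reported network sizes, a probability-proportional-to-size
    recruitment simulator with known ground truth, expert-benchmark fit
    classification (Great/Good/Okay/Bad), degree-depletion diagnostics, and
    the service multiplier, unique-object multiplier and wisdom-of-the-crowds
    comparison estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
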