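Package: crdp
Title: Constrained Randomised Dynamic Programming Designs for
    Response-Adaptive Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of bandit-based response-adaptive
    randomisation for two-armed clinical trials with binary endpoints.
    Solves the finite-horizon Bayesian Bernoulli two-armed bandit by
    backward induction and extends the optimal dynamic-programming (DP)
    allocation with randomised actions (degree of randomisation p) and a
    terminal penalty enforcing a minimum per-arm sample size (degree of
    constraining), yielding the constrained randomised dynamic
    programming (CRDP) design. Includes fixed equal randomisation and
    the randomised play-the-winner urn as comparators, a reproducible
    trial simulator, and evaluation of operating characteristics (power,
    type I error, patient benefit, bias and mean squared error of the
    treatment-effect estimator) over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
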