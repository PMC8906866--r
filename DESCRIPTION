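Package: conchsim
Title: Individual-Based Simulation of Queen Conch Mating and Spawning Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based model of queen conch (Lobatus gigas)
    reproductive dynamics in a one-hectare arena: daily isotropic random-walk
    movement with truncated-normal speeds, optional scent-tracking attraction
    (Barnes-Hut n-body approximation), movement barriers, perception-distance
    based encounter detection between daily paths, a sexual-facilitation mating
    gate, interbreeding rest periods, and oogenesis-delayed spawning. Includes
    a factorial design runner with reproducible seeding, replicate aggregation
    with confidence bands, and a comparison stage that fits censored
    log-logistic (ED50) and asymptotic dose-response regressions to
    density-reproduction observations and classifies mechanistic simulations
    as superior or inferior fits via goodness-of-fit statistics and
    Bonferroni-corrected paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
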