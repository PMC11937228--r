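Package: vjump
Title: Velocity-Jump Process Models for Discrete-Time Noisy Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and approximate likelihood analysis of n-state
    one-dimensional velocity-jump models observed as discrete-time, noisy
    single-agent tracks. The hidden state follows a continuous-time Markov
    chain; each state carries a fixed velocity. The package provides an exact
    (Gillespie) simulator with a Gaussian observation model, analytic
    up-to-one-switch and up-to-two-switch approximations to the distribution
    of a noisy location increment, a forward-filter approximation to the joint
    track density with hidden-state filtering, and maximum-likelihood fitting
    utilities. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
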