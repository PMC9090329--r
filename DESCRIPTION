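Package: socbandit
Title: Conformist Social Learning and Collective Rescue in Risky Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how conformist social learning reshapes
    risky decision making in multi-armed bandit tasks. Provides an
    agent-based simulator of Rescorla-Wagner/softmax learners with
    frequency-dependent (conformist) social influence, including the
    decision-biasing and value-shaping variants; a reduced
    differential-equation model of the collective dynamics with
    equilibrium and bifurcation analysis; a synthetic-experiment
    generator emulating group bandit studies; and hierarchical Bayesian
    model fitting with WAIC-based random-effects model selection,
    parameter-recovery harnesses, and posterior predictive simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    yaml,
    jsonlite,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
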