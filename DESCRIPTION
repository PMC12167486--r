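Package: commutegame
Title: Day-to-Day Commuting Route-Choice Games with Behavioral and Learning Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of repeated commuting route-choice games on
    a two origin-destination network with congestible routes. Travel costs follow
    the Bureau of Public Roads (BPR) volume-delay function; discrete user
    equilibrium and system optimum are certified by exhaustive enumeration.
    Multi-day trials (default 40 days of 4 decision intervals) are played by
    pluggable agent policies: win-stay/lose-shift behavioral archetypes,
    inertial best response, independent advantage actor-critic reinforcement
    learners (pretrain-then-freeze), and a mockable text-protocol adapter.
    Analysis tools cover Sorensen-Dice convergence to equilibrium, route-switch
    dynamics, cost-versus-switching regression, and classification of agents
    into naive, strategic, exploratory and status-quo decision types, together
    with a synthetic-population generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
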