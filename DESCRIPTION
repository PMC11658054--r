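Package: queenrelay
Title: Queen Pheromone Relay Networks from Honeybee Trajectory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the honeybee queen's non-volatile fertility
    signal spreads through a colony. From per-frame bee trajectories the package
    detects transmission-relevant physical contacts using trapezoidal body
    models, segments queen movement into stationary and travelling bouts with a
    two-state hidden Markov model, and simulates stochastic pheromone
    transmission over the time-ordered contact sequence (licking/antennation
    transfer, diminishing returns, leaky ingestion and decay). Downstream
    analyses cover audience dynamics, in-silico queen removal half-lives,
    receiver orientation difference maps via a specified-direction Rayleigh
    statistic, worker attraction tests, soft community detection with bridging
    scores, daily relay networks, an age-cohort donation hierarchy, and the
    developmental trajectory of the worker messaging syndrome. A seeded
    synthetic-colony generator provides ground-truthed test beds for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
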