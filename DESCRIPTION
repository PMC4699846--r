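Package: synturn
Title: Stochastic Compound-Connection Models of Synaptic Turnover and
    Long-Term Information Storage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Birth-death Markov models for the number of synapses in a
    multi-synapse ("compound") connection between two neurons. Deletion
    rates are inverted from target stationary distributions by detailed
    balance, so that low-, working-point- and high-stimulation conditions
    realize unimodal or bimodal synapse-count distributions. The package
    provides exact spectral propagation of the master equation, an
    event-driven stochastic simulator with per-site occupancy tracking for
    spine-turnover accounting, mutual-information decay analyses, a reduced
    two-state (peak-level) approximation with analytic matching of its
    transition rate, calibration of model time steps against experimental
    daily spine-turnover fractions, and the decay, learning/retention and
    retraining protocols used to study how long bistable synapse dynamics
    retain information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
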