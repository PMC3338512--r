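Package: moranmut
Title: Moran Processes with Structured Mutation Kernels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact evolutionary dynamics of finite populations under the Moran
    process when mutations are structured by an arbitrary mutation kernel.
    Computes fixation probabilities under the exponential payoff-to-fitness
    mapping (including the strong-selection limit), builds the embedded Markov
    chain over monomorphic states in the rare-mutation limit and solves its
    stationary distribution for any ergodic kernel, and evaluates abundance and
    risk-dominance conditions in 2x2 games. Ships two study systems in which
    kernel structure reshapes the evolution of cooperation: the eight
    memory-one strategies of the repeated prisoner's dilemma with a bitwise
    (Hamming-neighbour) kernel, and optional public goods games with
    punishment in the four-strategy and twenty-four-strategy spaces, including
    loner-biased and bitwise-like kernels. A compiled Monte Carlo Moran
    simulator validates the rare-mutation analytics at finite mutation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
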