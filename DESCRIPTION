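Package: evacgame
Title: Evolutionary Game Models of Typhoon Evacuation Decisions on Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how evacuation decisions spread through a
    population facing a predictable disaster such as a typhoon. Households
    choose between evacuating and staying at home; their payoffs depend on
    asset risk, evacuation and sheltering costs, and government policy levers
    that subsidise either choice. The package computes the two-player payoff
    matrix, analyses the mean-field replicator dynamics (expected payoffs,
    fixed points, Jacobian-based stability classification, phase-portrait
    integration), and simulates the corresponding imitation dynamic with a
    Fermi pairwise-comparison rule on Watts-Strogatz small-world networks.
    Parameter sweeps over the policy levers quantify how each intervention
    shifts the final evacuation response rate, with common random numbers and
    full seed provenance for reproducibility. A command-line interface exposes
    the main computations.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
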