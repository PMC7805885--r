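Package: meaculpa
Title: Evolutionary Dynamics of Guilty Apology in a Noisy Iterated
    Prisoner's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of guilt-driven apology as a behavioral
    strategy in an iterated prisoner's dilemma with execution errors.
    Computes exact expected encounter payoffs for apologizing ("guilt-prone"
    grim trigger), faking, grim-trigger, and unconditional strategies via a
    Markov-chain linear solve, cross-validated by Monte-Carlo simulation;
    certifies evolutionarily stable strategies; locates ESS boundaries in
    apology cost and interaction length; and estimates basins of attraction
    under discrete-time replicator dynamics, including the apology cost that
    maximizes the evolvability of guilt when apologies are fakeable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
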