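Package: cuttlemem
Title: Episodic-Like Memory Simulation with a What/When/Where Value Tensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A parsimonious model of episodic-like memory: a three-dimensional
    expected-value tensor indexed by object identity (what), hour of day
    (when) and grid location (where), learned with the Rescorla-Wagner delta
    rule and read out through partial-index queries and softmax (Boltzmann)
    action selection. Includes two gridworld scenarios -- a cuttlefish
    delayed-reward foraging experiment and a predator-prey world with
    hide/hunt/roam actions under two memory-query policies -- together with
    analysis tools for choice fractions, outcome time courses, actions per
    hour, and "mental time travel" query tables over the learned memory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
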