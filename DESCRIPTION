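Package: multidiv
Title: Diversity of Multiplex Networks via Information-Theoretic Layer Distances
Version: 0.1.0
Authors@R:
    person("multidiv", "developers", email = "multidiv@example.org", role = c("aut", "cre"))
Description: Quantifies how different the layers of a multiplex network are,
    and how much each layer (or each node's per-layer connectivity) contributes
    to the diversity of the whole system. Distances between a node's
    connectivity profiles across layers combine Jensen-Shannon divergences
    between shortest-path distance distributions and one-step random-walk
    transition profiles; layer distances average these over nodes. On top of
    the resulting distance matrices, a Weitzman-style recursive diversity value
    is computed exactly by dynamic programming over subsets, a lexicographic
    greedy elimination produces a diversity ordering of elements, and a
    layer-reduction curve tracks the diversity retained as the least
    contributing layers are discarded. Includes readers and writers for
    multiplex edge lists and distance matrices, seeded synthetic generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
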