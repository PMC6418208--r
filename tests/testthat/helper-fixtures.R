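# small builders shared across test files

# two layers on nodes a..e: node "a" isolated in p, hub reaching all in q
extreme_node_net <- function() {
  nodes <- letters[1:5]
  multiplex_network(list(
    p = rbind(c("b", "c"), c("c", "d"), c("d", "e")),
    q = cbind("a", nodes[-1])
  ), nodes = nodes)
}

# complete layer vs edge-free layer on n nodes
complete_vs_empty_net <- function(n = 4) {
  nodes <- letters[seq_len(n)]
  multiplex_network(list(
    full = t(utils::combn(nodes, 2)),
    void = matrix(character(), ncol = 2)
  ), nodes = nodes)
}

# the 3-node hand-worked example: layer p = {a-b}, layer q = {a-b, a-c}
hand_example_net <- function() {
  multiplex_network(list(
    p = rbind(c("a", "b")),
    q = rbind(c("a", "b"), c("a", "c"))
  ), nodes = c("a", "b", "c"))
}

# frozen values recomputed with independent high-precision arithmetic before
# the implementation existed (see helper-oracles.R for the formulas)
HAND_D_A <- 0.5579230452841438
HAND_D_B <- 0.3535533905932738
HAND_LD <- 0.6371588119591393
JS_HALF <- 0.21576155433883565    # JS((1,0), (0.5,0.5))
H_3QUARTER <- 0.5623351446188083  # H(0.75, 0.25)
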