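test_that("element-to-set distance is the minimum over the set", {
  dm <- example_ld_matrix()
  expect_equal(element_set_distance(dm, "c", c("a", "b", "d")), 0.214)
  expect_equal(element_set_distance(dm, "a", "d"), 0.786)
  expect_error(element_set_distance(dm, "a", c("a", "b")), "must not belong")
  expect_error(element_set_distance(dm, "a", character()), "non-empty")
  expect_error(element_set_distance(dm, "zz", "a"), "unknown")

  set.seed(3)
  m <- random_sym_matrix(6)
  for (g in rownames(m)) {
    s <- setdiff(rownames(m), g)[sample(1:5, 3)]
    expect_equal(element_set_distance(m, g, s), min(m[g, s]))
  }
})

test_that("exact diversity reproduces the worked example in full", {
  rep <- diversity_exact(example_ld_matrix())
  expect_equal(rep$value, 1.692, tolerance = 1e-9)
  expect_equal(rep$increments, c(0.214, 0.692, 0.786), tolerance = 1e-9)
  expect_equal(rep$elimination_order, c("c", "b", "a"))
  expect_equal(rep$survivor, "d")
  expect_equal(rep$diversity_order, c("d", "a", "b", "c"))
  expect_equal(rep$method, "dp")
  expect_equal(sum(rep$increments), rep$value, tolerance = 1e-9)
  expect_equal(sum(rep$contributions), 1, tolerance = 1e-9)

  pair <- diversity_exact(example_ld_matrix()[c("a", "d"), c("a", "d")])
  expect_equal(pair$value, 0.786)

  singleton <- diversity_exact(matrix(0, 1, 1, dimnames = list("x", "x")))
  expect_equal(singleton$value, 0)
  expect_length(singleton$elimination_order, 0)
})

test_that("exact diversity equals the recursive oracle on random matrices", {
  set.seed(19)
  for (rep in 1:100) {
    k <- sample(3:7, 1)
    m <- random_sym_matrix(k)
    expect_equal(diversity_exact(m)$value, oracle_weitzman(m),
                 tolerance = 1e-12)
  }
})

test_that("the subset solver refuses sets above the capacity limit", {
  m <- random_sym_matrix(5)
  expect_error(diversity_exact(m, dp_limit = 4), "diversity_greedy")
})

test_that("greedy ordering reproduces the worked example and its conventions", {
  rep <- diversity_greedy(example_ld_matrix())
  expect_equal(rep$value, 1.692, tolerance = 1e-9)
  expect_equal(rep$elimination_order, c("c", "b", "a"))
  expect_equal(rep$increments, c(0.214, 0.692, 0.786), tolerance = 1e-9)
  expect_equal(rep$survivor, "d")
  expect_equal(rep$method, "greedy")

  # all-equal off-diagonals: value (K-1)*delta, ties broken by label
  k <- 5; delta <- 0.3
  m <- matrix(delta, k, k, dimnames = list(letters[1:k], letters[1:k]))
  diag(m) <- 0
  flat <- diversity_greedy(m)
  expect_equal(flat$value, (k - 1) * delta, tolerance = 1e-12)
  expect_equal(flat$elimination_order, letters[1:(k - 1)])
})

test_that("greedy never exceeds the exact value and is often close", {
  set.seed(23)
  ratio <- numeric()
  for (rep in 1:200) {
    m <- random_sym_matrix(sample(3:8, 1))
    g <- diversity_greedy(m)$value
    d <- diversity_exact(m)$value
    expect_lte(g, d + 1e-9)
    ratio <- c(ratio, g / d)
  }
  expect_gt(mean(ratio), 0.9)  # the heuristic tracks the exact value closely
})

test_that("global diversity composes the layer distance matrix", {
  same <- multiplex_network(list(p = rbind(c("a", "b")), q = rbind(c("a", "b")),
                                 r = rbind(c("a", "b"))))
  expect_equal(global_diversity(same)$value, 0)

  expect_equal(global_diversity(complete_vs_empty_net())$value, 1)

  net <- er_multiplex(8, 5, 0.3, seed = 31)
  expect_equal(global_diversity(net)$value,
               diversity_exact(layer_distance_matrix(net))$value,
               tolerance = 1e-12)
  # auto dispatch switches to greedy above the capacity limit
  expect_equal(global_diversity(net, "auto", dp_limit = 3)$method, "greedy")
  expect_equal(global_diversity(net, "auto", dp_limit = 10)$method, "dp")
})

test_that("node diversity handles extremes and matches composition", {
  iso <- multiplex_network(list(p = rbind(c("a", "b")), q = rbind(c("a", "b"))),
                           nodes = c("a", "b", "z"))
  expect_equal(node_diversity(iso, "z")$value, 0)
  expect_equal(node_diversity(extreme_node_net(), "a")$value, 1)

  net <- er_multiplex(7, 4, 0.4, seed = 37)
  v <- net$nodes[2]
  expect_equal(node_diversity(net, v)$value,
               diversity_exact(node_distance_matrix(net, v))$value,
               tolerance = 1e-12)
  expect_error(node_diversity(net, "ghost"), "unknown node")
})

test_that("per-node diversity is consistent and duplicate-layer invariant", {
  same <- multiplex_network(list(p = rbind(c("a", "b")), q = rbind(c("a", "b"))),
                            nodes = c("a", "b", "c"))
  expect_equal(unname(node_diversity_all(same)), rep(0, 3))

  net <- er_multiplex(6, 3, 0.4, seed = 41)
  ui <- node_diversity_all(net)
  expect_equal(names(ui), net$nodes)
  for (v in net$nodes) {
    expect_equal(ui[[v]], node_diversity(net, v)$value, tolerance = 1e-12)
  }

  doubled <- multiplex_network(c(net$edges, stats::setNames(net$edges,
                                                            paste0(net$layers, "_copy"))),
                               nodes = net$nodes)
  expect_equal(unname(node_diversity_all(doubled)), unname(ui),
               tolerance = 1e-9)
})

test_that("reduction curve follows the worked example and is monotone", {
  curve <- reduction_curve(example_ld_matrix())
  expect_equal(curve$U, c(1.692, 1.478, 0.786, 0), tolerance = 1e-9)
  expect_equal(curve$removed, c(NA, "c", "b", "a"))
  expect_equal(curve$retained_size, 4:1)
  expect_equal(curve$loss_fraction[1], 0)
  expect_equal(curve$loss_fraction[4], 1)

  set.seed(47)
  for (rep in 1:25) {
    m <- random_sym_matrix(sample(3:7, 1))
    cv <- reduction_curve(m)
    expect_true(all(diff(cv$U) <= 1e-12))
    expect_true(all(diff(cv$loss_fraction) >= -1e-12))
    expect_equal(cv$U[nrow(cv)], 0)
  }
})
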