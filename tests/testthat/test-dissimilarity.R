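test_that("shannon entropy handles the standard cases", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 7, 7)), log(7))
  expect_equal(shannon_entropy(c(0.75, 0.25)), H_3QUARTER, tolerance = 1e-15)
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum")
  expect_error(shannon_entropy(c(1.2, -0.2)), "negative")
})

test_that("js divergence matches hand values and direct formula", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), JS_HALF, tolerance = 1e-15)
  expect_error(js_divergence(c(a = 1), c(b = 1)), "outcome")
  expect_error(js_divergence(c(1, 0), c(0.5, 0.25, 0.25)), "aligned")
  # named alignment is order-free
  expect_equal(js_divergence(c(a = 0.2, b = 0.8), c(b = 0.8, a = 0.2)), 0)

  set.seed(42)
  for (rep in 1:200) {
    k <- sample(2:10, 1)
    p <- random_distribution(k)
    q <- random_distribution(k)
    expect_equal(js_divergence(p, q), oracle_js(p, q), tolerance = 1e-12)
  }
})

test_that("node difference reproduces the hand-worked 3-node example", {
  net <- hand_example_net()
  res <- node_difference(net, "a", "p", "q")
  expect_equal(res$ndd_term, JS_HALF, tolerance = 1e-12)
  expect_equal(res$transition_term, JS_HALF, tolerance = 1e-12)
  expect_equal(res$value, HAND_D_A, tolerance = 1e-12)
  expect_equal(node_difference(net, "b", "p", "q")$value, HAND_D_B,
               tolerance = 1e-12)
  expect_equal(node_difference(net, "c", "p", "q")$value, 1)
  expect_equal(layer_difference(net, "p", "q"), HAND_LD, tolerance = 1e-12)
  # internal consistency of the combination rule
  expect_equal(res$value,
               (sqrt(res$ndd_term) + sqrt(res$transition_term)) /
                 (2 * sqrt(log(2))), tolerance = 1e-12)
})

test_that("identical layers and extreme configurations hit the bounds", {
  same <- multiplex_network(list(p = rbind(c("a", "b")), q = rbind(c("a", "b"))),
                            nodes = c("a", "b", "c"))
  expect_equal(node_difference(same, "a", "p", "q")$value, 0)
  expect_equal(layer_difference(same, "p", "q"), 0)

  ext <- extreme_node_net()
  expect_equal(node_difference(ext, "a", "p", "q")$value, 1)

  cve <- complete_vs_empty_net(4)
  expect_equal(layer_difference(cve, "full", "void"), 1)
})

test_that("results are symmetric in the layer pair, bit for bit", {
  net <- er_multiplex(10, 3, 0.3, seed = 9)
  for (v in net$nodes[1:3]) {
    a <- node_difference(net, v, "L1", "L2")
    b <- node_difference(net, v, "L2", "L1")
    expect_identical(a$value, b$value)
    expect_identical(a$ndd_term, b$ndd_term)
  }
  expect_identical(layer_difference(net, "L1", "L3"),
                   layer_difference(net, "L3", "L1"))
})

test_that("distance matrices match entrywise recomputation", {
  net <- er_multiplex(8, 4, 0.35, seed = 13)
  ldm <- layer_distance_matrix(net)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(ldm[i, j],
                   layer_difference(net, net$layers[i], net$layers[j]),
                   tolerance = 1e-12)
    }
  }
  ndm <- node_distance_matrix(net, net$nodes[1])
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(ndm[i, j],
                   node_difference(net, net$nodes[1], net$layers[i],
                                   net$layers[j])$value, tolerance = 1e-12)
    }
  }

  single <- multiplex_network(list(only = rbind(c("a", "b"))))
  expect_equal(unclass(layer_distance_matrix(single)),
               matrix(0, 1, 1, dimnames = list("only", "only")),
               ignore_attr = TRUE)

  # duplicated layer: its row/column pair must coincide
  dup <- multiplex_network(list(p = rbind(c("a", "b")), q = rbind(c("a", "b")),
                                r = rbind(c("b", "c"))),
                           nodes = c("a", "b", "c"))
  dd <- layer_distance_matrix(dup)
  expect_identical(dd["p", "r"], dd["q", "r"])
  expect_equal(dd["p", "q"], 0)
})

test_that("node distance matrix extremes", {
  iso <- multiplex_network(list(p = rbind(c("a", "b")), q = rbind(c("b", "a"))),
                           nodes = c("a", "b", "z"))
  expect_equal(max(node_distance_matrix(iso, "z")), 0)
  ext <- extreme_node_net()
  expect_equal(node_distance_matrix(ext, "a")["p", "q"], 1)
})

test_that("differences stay in [0, 1] on random multiplexes", {
  # scaled down from the spec'd 1000 fixtures to keep the default run fast;
  # the matrix-level property suite in test-acceptance.R covers the full count
  set.seed(77)
  for (rep in 1:60) {
    net <- er_multiplex(sample(4:10, 1), sample(2:4, 1), stats::runif(1),
                        seed = sample.int(1e6, 1))
    ldm <- layer_distance_matrix(net)
    expect_true(all(ldm >= 0 & ldm <= 1))
  }
})
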