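#' Seeded multilayer Erdős–Rényi generator
#'
#' Draws `n_layers` independent G(n, p) layers on a shared node set. The
#' sampling algorithm is fixed so fixtures are reproducible across platforms:
#' for each layer in label order, one uniform deviate is drawn per unordered
#' node pair in row-major label order `(1,2), (1,3), ..., (N-1,N)`, and the
#' edge is present iff the deviate is below `edge_probability`. The caller's
#' RNG state is left untouched.
#'
#' @param n_nodes number of nodes (labels `n01, n02, ...`)
#' @param n_layers number of layers (labels `L1, L2, ...`)
#' @param edge_probability per-pair edge probability in `[0, 1]`
#' @param seed integer seed; the same spec always yields the identical network
#' @param node_labels,layer_labels optional label overrides
#' @return a [multiplex_network()]
#' @examples
#' er_multiplex(10, 3, 0.3, seed = 1)
#' @export
er_multiplex <- function(n_nodes, n_layers, edge_probability, seed,
                         node_labels = NULL, layer_labels = NULL) {
  stopifnot(n_nodes >= 1, n_layers >= 1,
            edge_probability >= 0, edge_probability <= 1)
  if (is.null(node_labels)) {
    node_labels <- sprintf("n%0*d", nchar(as.character(n_nodes)),
                           seq_len(n_nodes))
  }
  if (is.null(layer_labels)) layer_labels <- paste0("L", seq_len(n_layers))
  stopifnot(length(node_labels) == n_nodes, length(layer_labels) == n_layers)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  pairs <- if (n_nodes > 1) t(utils::combn(node_labels, 2)) else
    matrix(character(), ncol = 2)
  edges <- stats::setNames(lapply(seq_len(n_layers), function(m) {
    if (nrow(pairs) == 0) return(matrix(character(), ncol = 2))
    keep <- stats::runif(nrow(pairs)) < edge_probability
    pairs[keep, , drop = FALSE]
  }), layer_labels)
  multiplex_network(edges, nodes = node_labels, layers = layer_labels)
}

#' Bundled 4-element worked-example distance matrix
#'
#' The small pairwise layer-distance matrix used throughout the documentation
#' and tests to illustrate the diversity recursion: labels `a, b, c, d` with
#' `D(a,b) = 0.697`, `D(a,c) = 0.214`, `D(a,d) = 0.786`, `D(b,c) = 0.580`,
#' `D(b,d) = 0.692`, `D(c,d) = 0.804`. Its exact diversity is
#' `0.214 + 0.692 + 0.786 = 1.692`, with `c` removed first and `b` second.
#'
#' @return a 4x4 [distance_matrix()]
#' @examples
#' diversity_exact(example_ld_matrix())$value
#' @export
example_ld_matrix <- function() {
  labs <- c("a", "b", "c", "d")
  v <- matrix(0, 4, 4, dimnames = list(labs, labs))
  v["a", "b"] <- 0.697
  v["a", "c"] <- 0.214
  v["a", "d"] <- 0.786
  v["b", "c"] <- 0.580
  v["b", "d"] <- 0.692
  v["c", "d"] <- 0.804
  distance_matrix(v + t(v), labs)
}

#' Bundled 6-node, 4-layer demonstration multiplex
#'
#' A small hand-built multiplex used to demonstrate how single-link changes
#' move the global diversity: the link `5-6` is present in layers `a`, `c`
#' and `d` but not `b` (adding it to `b` is redundant and lowers diversity),
#' while the link `3-6` is absent from every layer and node `3` is a
#' peripheral pendant in layer `c` (adding `3-6` there gives node `3` a new
#' connection pattern found in no other layer and raises diversity).
#'
#' @return a [multiplex_network()] with nodes `1..6` and layers `a, b, c, d`
#' @export
example_multiplex <- function() {
  ring <- rbind(c("1", "2"), c("2", "3"), c("3", "4"), c("4", "5"),
                c("5", "6"), c("1", "6"))
  multiplex_network(list(
    a = ring,
    b = ring[-5, ],                                  # ring without 5-6
    c = rbind(c("1", "2"), c("2", "5"), c("5", "6"), c("1", "6"),
              c("3", "4"), c("4", "5")),             # node 3 pendant on 4
    d = rbind(ring, c("1", "4"))                     # ring plus a chord
  ), nodes = as.character(1:6))
}

#' Add or remove a single link in one layer
#'
#' Returns a copy of the network with exactly one modification. Requesting a
#' modification that would be a no-op (adding an existing edge, removing an
#' absent one) is an error, as is a self-loop.
#'
#' @param net a [multiplex_network()]
#' @param layer layer label
#' @param u,v node labels, `u != v`; nodes not yet in the network are added
#'   to the shared node set when adding a link
#' @param mode `"add"` or `"remove"`
#' @return the modified [multiplex_network()]
#' @examples
#' net <- example_multiplex()
#' perturb_link(net, "b", "5", "6", "add")
#' @export
perturb_link <- function(net, layer, u, v, mode = c("add", "remove")) {
  stopifnot(inherits(net, "multiplex_network"))
  mode <- match.arg(mode)
  check_layer(net, layer)
  u <- trimws(u)
  v <- trimws(v)
  if (u == v) stop("self-loops are not allowed", call. = FALSE)
  a <- min(u, v)
  b <- max(u, v)
  e <- net$edges[[layer]]
  present <- nrow(e) > 0 && any(e[, 1] == a & e[, 2] == b)
  if (mode == "add") {
    if (present) stop("edge ", a, "-", b, " already present in layer '",
                      layer, "'", call. = FALSE)
    e <- rbind(e, c(a, b))
  } else {
    check_node(net, u)
    check_node(net, v)
    if (!present) stop("edge ", a, "-", b, " absent from layer '", layer, "'",
                       call. = FALSE)
    e <- e[!(e[, 1] == a & e[, 2] == b), , drop = FALSE]
  }
  edges <- net$edges
  edges[[layer]] <- e
  multiplex_network(edges, nodes = net$nodes, layers = net$layers)
}
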