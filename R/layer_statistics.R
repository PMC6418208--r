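#' @useDynLib multidiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

UNREACHABLE <- "UNREACHABLE"
INACTIVE <- "<INACTIVE>"

ndd_bins <- function(n) {
  if (n <= 1) return(UNREACHABLE)
  c(as.character(seq_len(n - 1)), UNREACHABLE)
}

# all node distance distributions of one layer: N x N matrix,
# rows = nodes, cols = bins {1, ..., N-1, UNREACHABLE}
ndd_profiles <- function(net, layer) {
  n <- length(net$nodes)
  bins <- ndd_bins(n)
  out <- matrix(0, n, length(bins), dimnames = list(net$nodes, bins))
  if (n == 1) {
    out[, UNREACHABLE] <- 1
    return(out)
  }
  d <- igraph::distances(layer_graph(net, layer))
  d <- d[net$nodes, net$nodes, drop = FALSE]
  for (i in seq_len(n)) {
    di <- d[i, -i]
    finite <- di[is.finite(di)]
    if (length(finite) > 0) {
      tab <- tabulate(as.integer(finite), nbins = n - 1)
      out[i, seq_len(n - 1)] <- tab / (n - 1)
    }
    out[i, UNREACHABLE] <- (n - 1 - length(finite)) / (n - 1)
  }
  out
}

# all transition profiles of one layer: N x (N+1) matrix,
# rows = walkers, cols = node labels plus the INACTIVE sentinel
transition_profiles <- function(net, layer) {
  if (INACTIVE %in% net$nodes) {
    stop("node label '", INACTIVE, "' collides with the inactivity sentinel",
         call. = FALSE)
  }
  a <- layer_adjacency(net, layer)
  deg <- rowSums(a)
  n <- length(net$nodes)
  out <- cbind(a, 0)
  colnames(out) <- c(net$nodes, INACTIVE)
  active <- deg > 0
  out[active, ] <- out[active, , drop = FALSE] / deg[active]
  out[!active, INACTIVE] <- 1
  out
}

#' Node distance distribution of a node in one layer
#'
#' The fraction of the other `N - 1` nodes at each shortest-path distance
#' from `node` in `layer`. Unreachable nodes (including all of them, when the
#' node is inactive in the layer) are pooled in a dedicated `UNREACHABLE` bin;
#' the node itself is excluded, so the mass vector always sums to 1.
#'
#' @param net a [multiplex_network()]
#' @param node node label
#' @param layer layer label
#' @return an object of class `distance_profile`: list with `node`, `layer`
#'   and `mass`, a named vector over bins `1, ..., N-1, UNREACHABLE`
#' @examples
#' net <- multiplex_network(list(L = rbind(c("a", "b"), c("b", "c"))))
#' node_distance_distribution(net, "a", "L")$mass
#' @export
node_distance_distribution <- function(net, node, layer) {
  check_node(net, node)
  check_layer(net, layer)
  m <- ndd_profiles(net, layer)
  structure(list(node = node, layer = layer, mass = m[node, ]),
            class = "distance_profile")
}

#' One-step random-walk transition profile of a node in one layer
#'
#' For a node of degree `k > 0` the profile puts mass `1/k` on each neighbor.
#' An inactive node (degree 0) has no walk step; its profile is a point mass
#' on a reserved `<INACTIVE>` outcome, disjoint from every node label, so
#' that an inactive profile has disjoint support from any active one.
#'
#' @inheritParams node_distance_distribution
#' @return an object of class `transition_profile`: list with `node`, `layer`
#'   and `mass`, a named vector over all node labels plus `<INACTIVE>`
#' @export
transition_profile <- function(net, node, layer) {
  check_node(net, node)
  check_layer(net, layer)
  m <- transition_profiles(net, layer)
  structure(list(node = node, layer = layer, mass = m[node, ]),
            class = "transition_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("Distance distribution of node '", x$node, "' in layer '", x$layer,
      "'\n", sep = "")
  print(round(x$mass[x$mass > 0], 4))
  invisible(x)
}

#' @export
print.transition_profile <- function(x, ...) {
  cat("Transition profile of node '", x$node, "' in layer '", x$layer,
      "'\n", sep = "")
  print(round(x$mass[x$mass > 0], 4))
  invisible(x)
}
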