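#' Shannon entropy of a discrete distribution (nats)
#'
#' `-sum(p * log(p))` with the usual convention `0 * log(0) = 0`. Entries must
#' be non-negative and sum to 1 within `1e-9`.
#'
#' @param p numeric vector of probabilities
#' @return entropy in nats
#' @examples
#' shannon_entropy(c(0.75, 0.25))
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("negative probability mass", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probabilities sum to ", format(sum(p)), ", not 1", call. = FALSE)
  }
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Jensen-Shannon divergence between two aligned distributions (nats)
#'
#' `H((p+q)/2) - (H(p) + H(q))/2`. Symmetric, zero iff `p == q`, bounded by
#' `log(2)` with equality iff the supports are disjoint. If both vectors are
#' named they are aligned by name and must share the same outcome set;
#' unnamed vectors are aligned positionally and must have equal length.
#'
#' @param p,q numeric probability vectors
#' @return divergence in nats, in `[0, log(2)]`
#' @examples
#' js_divergence(c(1, 0), c(0.5, 0.5))
#' @export
js_divergence <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q))) {
      stop("distributions are defined over different outcome sets", call. = FALSE)
    }
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("distributions must share an aligned outcome set", call. = FALSE)
  }
  hp <- shannon_entropy(p)
  hq <- shannon_entropy(q)
  hm <- shannon_entropy((as.numeric(p) + as.numeric(q)) / 2)
  min(max(hm - (hp + hq) / 2, 0), log(2))
}

# JS divergence row-by-row between two matrices of distributions
js_rows <- function(p, q) {
  h <- function(x) {
    x[x <= 0] <- 1  # log(1) = 0 stands in for 0*log(0)
    -rowSums(x * log(x))
  }
  pmin(pmax(h((p + q) / 2) - (h(p) + h(q)) / 2, 0), log(2))
}

#' Node difference between two layers
#'
#' Distance in `[0, 1]` between the connectivity of one node in two layers:
#' the Jensen-Shannon divergence between its shortest-path distance
#' distributions and between its one-step transition profiles, combined as
#' `(sqrt(J_ndd) + sqrt(J_trans)) / (2 * sqrt(log(2)))`. It is 0 when the
#' node's connectivity paths are identical in both layers, and 1 when the
#' node is inactive in one layer while reaching every node in the other.
#'
#' @param net a [multiplex_network()]
#' @param node node label
#' @param layer_p,layer_q layer labels
#' @return an object of class `node_difference`: list with `node`,
#'   `layer_pair`, the two divergence terms (nats) and `value` in `[0, 1]`
#' @examples
#' net <- multiplex_network(list(p = rbind(c("a", "b")),
#'                               q = rbind(c("a", "b"), c("a", "c"))))
#' node_difference(net, "a", "p", "q")$value
#' @export
node_difference <- function(net, node, layer_p, layer_q) {
  check_node(net, node)
  nddp <- node_distance_distribution(net, node, layer_p)$mass
  nddq <- node_distance_distribution(net, node, layer_q)$mass
  trp <- transition_profile(net, node, layer_p)$mass
  trq <- transition_profile(net, node, layer_q)$mass
  j_ndd <- js_divergence(nddp, nddq)
  j_tr <- js_divergence(trp, trq)
  structure(
    list(node = node, layer_pair = c(layer_p, layer_q),
         ndd_term = j_ndd, transition_term = j_tr,
         value = (sqrt(j_ndd) + sqrt(j_tr)) / (2 * sqrt(log(2)))),
    class = "node_difference"
  )
}

#' @export
print.node_difference <- function(x, ...) {
  cat("Node '", x$node, "' difference between layers '", x$layer_pair[1],
      "' and '", x$layer_pair[2], "': ", round(x$value, 4), "\n", sep = "")
  invisible(x)
}

# per-node difference values between two layers, vectorized over nodes
node_difference_all <- function(net, layer_p, layer_q) {
  j_ndd <- js_rows(ndd_profiles(net, layer_p), ndd_profiles(net, layer_q))
  j_tr <- js_rows(transition_profiles(net, layer_p),
                  transition_profiles(net, layer_q))
  stats::setNames((sqrt(j_ndd) + sqrt(j_tr)) / (2 * sqrt(log(2))), net$nodes)
}

#' Layer difference between two layers
#'
#' The mean of [node_difference()] over all `N` nodes (nodes inactive in both
#' layers contribute 0). A distance between labeled layers in `[0, 1]`: 0 for
#' identical edge sets, 1 for a complete layer against an edge-free one.
#'
#' @inheritParams node_difference
#' @return numeric in `[0, 1]`
#' @export
layer_difference <- function(net, layer_p, layer_q) {
  check_layer(net, layer_p)
  check_layer(net, layer_q)
  mean(node_difference_all(net, layer_p, layer_q))
}

#' All pairwise layer differences of a multiplex network
#'
#' @param net a [multiplex_network()]
#' @return an `M x M` [distance_matrix()] of [layer_difference()] values
#' @export
layer_distance_matrix <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  m <- length(net$layers)
  ndd <- lapply(net$layers, function(l) ndd_profiles(net, l))
  tr <- lapply(net$layers, function(l) transition_profiles(net, l))
  out <- matrix(0, m, m, dimnames = list(net$layers, net$layers))
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        v <- mean((sqrt(js_rows(ndd[[i]], ndd[[j]])) +
                     sqrt(js_rows(tr[[i]], tr[[j]]))) / (2 * sqrt(log(2))))
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  distance_matrix(pmin(out, 1), net$layers)
}

#' Pairwise per-layer differences of a single node
#'
#' @param net a [multiplex_network()]
#' @param node node label
#' @return an `M x M` [distance_matrix()] of [node_difference()] values for
#'   the fixed node
#' @export
node_distance_matrix <- function(net, node) {
  check_node(net, node)
  m <- length(net$layers)
  out <- matrix(0, m, m, dimnames = list(net$layers, net$layers))
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        v <- node_difference(net, node, net$layers[i], net$layers[j])$value
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  distance_matrix(pmin(out, 1), net$layers)
}
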