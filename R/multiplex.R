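#' Construct a multiplex network
#'
#' A multiplex network is a set of `M` simple undirected layers sharing one
#' labeled node set of size `N`. Nodes absent from a layer's edge list are
#' still members of that layer, as isolated ("inactive") nodes. Node identity
#' across layers is by string label; labels are case-sensitive and stripped of
#' surrounding whitespace.
#'
#' @param edges named list, one element per layer, each a two-column character
#'   matrix (or data.frame) of node-label pairs. Self-loops and duplicate
#'   edges are dropped with a warning. A layer may have zero edges.
#' @param nodes optional character vector of node labels; the node set is the
#'   union of these and every label appearing in `edges`.
#' @param layers optional character vector fixing layer order; defaults to
#'   `names(edges)`.
#' @return An object of class `multiplex_network` with components `nodes`
#'   (sorted labels), `layers` (layer labels in order) and `edges` (per layer,
#'   a two-column character matrix in canonical order).
#' @examples
#' net <- multiplex_network(list(
#'   L1 = rbind(c("a", "b")),
#'   L2 = rbind(c("b", "c"))
#' ))
#' net
#' @export
multiplex_network <- function(edges, nodes = NULL, layers = NULL) {
  if (is.null(layers)) layers <- names(edges)
  if (is.null(layers) || any(!nzchar(layers))) {
    stop("every layer must have a non-empty label", call. = FALSE)
  }
  layers <- trimws(as.character(layers))
  if (anyDuplicated(layers)) {
    stop("duplicate layer labels: ",
         paste(unique(layers[duplicated(layers)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(layers) != length(edges)) {
    stop("'layers' and 'edges' lengths differ", call. = FALSE)
  }
  edges <- lapply(edges, function(e) {
    if (is.null(e) || (is.matrix(e) && nrow(e) == 0) ||
        (is.data.frame(e) && nrow(e) == 0) || length(e) == 0) {
      return(matrix(character(), ncol = 2))
    }
    e <- as.matrix(e)
    if (ncol(e) != 2) stop("edge tables must have two columns", call. = FALSE)
    matrix(trimws(as.character(e)), ncol = 2)
  })
  all_nodes <- unique(c(
    if (!is.null(nodes)) trimws(as.character(nodes)) else character(),
    unlist(edges, use.names = FALSE)
  ))
  if (length(all_nodes) < 1) stop("network must have at least one node", call. = FALSE)
  all_nodes <- sort(all_nodes)

  n_loops <- 0L
  n_dups <- 0L
  edges <- lapply(edges, function(e) {
    if (nrow(e) == 0) return(e)
    loops <- e[, 1] == e[, 2]
    n_loops <<- n_loops + sum(loops)
    e <- e[!loops, , drop = FALSE]
    if (nrow(e) == 0) return(e)
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste0(e[, 1], "\r", e[, 2])
    n_dups <<- n_dups + sum(duplicated(key))
    e <- e[!duplicated(key), , drop = FALSE]
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  })
  if (n_loops > 0) warning(n_loops, " self-loop(s) dropped", call. = FALSE)
  if (n_dups > 0) warning(n_dups, " duplicate edge(s) dropped", call. = FALSE)

  names(edges) <- layers
  structure(
    list(nodes = all_nodes, layers = layers, edges = edges),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("Multiplex network: ", length(x$nodes), " nodes, ",
      length(x$layers), " layers\n", sep = "")
  for (l in x$layers) {
    cat("  ", l, ": ", nrow(x$edges[[l]]), " edges\n", sep = "")
  }
  invisible(x)
}

#' Number of nodes / layers in a multiplex network
#' @param net a `multiplex_network`
#' @return an integer count
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  length(net$nodes)
}

#' @rdname n_nodes
#' @export
n_layers <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  length(net$layers)
}

#' @export
`==.multiplex_network` <- function(e1, e2) {
  identical(e1$nodes, e2$nodes) &&
    identical(e1$layers, e2$layers) &&
    all(vapply(e1$layers, function(l) identical(e1$edges[[l]], e2$edges[[l]]),
               logical(1)))
}

check_layer <- function(net, layer) {
  if (!layer %in% net$layers) {
    stop("unknown layer: '", layer, "'", call. = FALSE)
  }
  invisible(layer)
}

check_node <- function(net, node) {
  if (!node %in% net$nodes) {
    stop("unknown node: '", node, "'", call. = FALSE)
  }
  invisible(node)
}

#' Extract one layer as an igraph graph on the full node set
#'
#' @param net a `multiplex_network`
#' @param layer layer label
#' @return an undirected `igraph` graph whose vertices are all `N` nodes of
#'   the multiplex (inactive nodes included as isolates)
#' @export
layer_graph <- function(net, layer) {
  check_layer(net, layer)
  e <- net$edges[[layer]]
  igraph::graph_from_data_frame(
    data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

# adjacency of one layer as a dense 0/1 matrix with node labels
layer_adjacency <- function(net, layer) {
  check_layer(net, layer)
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges[[layer]]
  if (nrow(e) > 0) {
    i <- match(e[, 1], net$nodes)
    j <- match(e[, 2], net$nodes)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}
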