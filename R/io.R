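#' Construct a validated pairwise distance matrix
#'
#' Container for symmetric distances between elements (layers, or one node's
#' per-layer connectivity profiles). Entries must lie in `[0, 1]` with an
#' exactly zero diagonal; asymmetries up to `1e-9` are averaged away, larger
#' ones are an error.
#'
#' @param values square numeric matrix
#' @param labels element labels; defaults to `rownames(values)`
#' @return an object of class `pairwise_distance_matrix`: the numeric matrix
#'   with `dimnames` set to the labels
#' @export
distance_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("distance matrix must be square, got ", nrow(values), "x", ncol(values),
         call. = FALSE)
  }
  if (is.null(labels)) stop("element labels are required", call. = FALSE)
  labels <- trimws(as.character(labels))
  if (length(labels) != nrow(values) || anyDuplicated(labels)) {
    stop("labels must be unique and match the matrix dimension", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("distance matrix contains missing values", call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > 1e-9) {
    stop("matrix is asymmetric (max deviation ", format(asym), " > 1e-9)",
         call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(abs(diag(values)) > 1e-12)) {
    stop("diagonal entries must be zero", call. = FALSE)
  }
  diag(values) <- 0
  if (any(values < 0)) stop("negative distances are not allowed", call. = FALSE)
  if (any(values > 1)) stop("distances must not exceed 1", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("pairwise_distance_matrix", "matrix", "array"))
}

#' @export
print.pairwise_distance_matrix <- function(x, ...) {
  cat("Pairwise distance matrix over ", nrow(x), " elements\n", sep = "")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

# accept either the validated class or a plain symmetric non-negative matrix
# (diversity values are scale-equivariant, so entries above 1 are legal there)
as_distance_input <- function(dm) {
  if (inherits(dm, "pairwise_distance_matrix")) return(unclass(dm))
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(dm))) {
    dimnames(dm) <- list(as.character(seq_len(nrow(dm))),
                         as.character(seq_len(nrow(dm))))
  }
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix must be symmetric", call. = FALSE)
  if (any(dm < 0)) stop("distances must be non-negative", call. = FALSE)
  dm
}

#' Read a multiplex network from an edge-list file
#'
#' Two dialects are supported. `"single-file"` is an extended edge list with
#' records `layer u v [w]` (whitespace- or comma-separated); `#`-comments are
#' allowed, a line `#LAYER <label>` declares a layer explicitly so that
#' edge-free layers survive round trips, and `#NODE <label>` declares a node
#' that appears in no edge. `"per-layer-directory"` reads every
#' `<layer>.edges` file in a directory, each a two-column node-pair list.
#'
#' The node set is the union of all labels seen anywhere; a node missing from
#' a layer is present there as an isolate. Weights, duplicate edges and
#' self-loops are dropped with a warning (shortest-path and degree-rescaled
#' profiles are defined on simple unweighted layers).
#'
#' @param path file (single-file dialect) or directory (per-layer dialect)
#' @param dialect `"single-file"` or `"per-layer-directory"`
#' @return a [multiplex_network()]
#' @export
read_multiplex_edgelist <- function(path,
                                    dialect = c("single-file", "per-layer-directory")) {
  dialect <- match.arg(dialect)
  if (dialect == "per-layer-directory") {
    if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.edges$", full.names = TRUE))
    if (length(files) == 0) stop("no *.edges files in ", path, call. = FALSE)
    layers <- sub("\\.edges$", "", basename(files))
    if (anyDuplicated(layers)) {
      stop("duplicate layer label across per-layer files", call. = FALSE)
    }
    edges <- lapply(files, read_layer_file)
    names(edges) <- layers
    return(multiplex_network(edges, layers = layers))
  }

  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meaningful <- FALSE
  layer_order <- character()
  declared_nodes <- character()
  recs <- list()
  weight_seen <- FALSE
  for (k in seq_along(lines)) {
    line <- trimws(lines[[k]])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#LAYER\\s+(\\S+)\\s*$", line))[[1]]
      if (length(m) == 2) {
        meaningful <- TRUE
        if (!m[2] %in% layer_order) layer_order <- c(layer_order, m[2])
      }
      m <- regmatches(line, regexec("^#NODE\\s+(\\S+)\\s*$", line))[[1]]
      if (length(m) == 2) {
        meaningful <- TRUE
        declared_nodes <- c(declared_nodes, m[2])
      }
      next
    }
    meaningful <- TRUE
    fields <- strsplit(line, "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3 || length(fields) > 4) {
      stop("malformed record at line ", k, ": '", lines[[k]], "'", call. = FALSE)
    }
    if (length(fields) == 4) {
      if (is.na(suppressWarnings(as.numeric(fields[4])))) {
        stop("malformed record at line ", k, ": non-numeric weight", call. = FALSE)
      }
      weight_seen <- TRUE
    }
    lay <- fields[1]
    if (!lay %in% layer_order) layer_order <- c(layer_order, lay)
    recs[[length(recs) + 1L]] <- fields[1:3]
  }
  if (!meaningful) stop("empty edge-list file: ", path, call. = FALSE)
  if (weight_seen) warning("weight column ignored", call. = FALSE)
  edges <- stats::setNames(
    lapply(layer_order, function(l) {
      rows <- Filter(function(r) r[1] == l, recs)
      if (length(rows) == 0) return(matrix(character(), ncol = 2))
      do.call(rbind, lapply(rows, function(r) r[2:3]))
    }),
    layer_order
  )
  multiplex_network(edges, nodes = declared_nodes, layers = layer_order)
}

read_layer_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rows <- list()
  for (k in seq_along(lines)) {
    line <- trimws(lines[[k]])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2) {
      stop("malformed record at line ", k, " of ", basename(file), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- fields[1:2]
  }
  if (length(rows) == 0) return(matrix(character(), ncol = 2))
  do.call(rbind, rows)
}

#' Write a multiplex network as a single-file edge list
#'
#' Emits the single-file dialect read by [read_multiplex_edgelist()]: layers
#' in label order, each preceded by a `#LAYER` declaration (so edge-free
#' layers are preserved), edges in canonical sorted order, and a `#NODE`
#' declaration for every node that appears in no edge at all (so globally
#' isolated nodes are preserved too). `read(write(net))` is the identity.
#'
#' @param net a `multiplex_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_multiplex_edgelist <- function(net, path) {
  stopifnot(inherits(net, "multiplex_network"))
  seen <- unique(unlist(net$edges, use.names = FALSE))
  out <- paste("#NODE", setdiff(net$nodes, seen))
  if (length(out) == 0) out <- character()
  for (l in net$layers) {
    out <- c(out, paste("#LAYER", l))
    e <- net$edges[[l]]
    if (nrow(e) > 0) out <- c(out, paste(l, e[, 1], e[, 2]))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a pairwise distance matrix from CSV
#'
#' Expects a header row of element labels and a label column; the body must be
#' square and numeric. Validation mirrors [distance_matrix()]: entries in
#' `[0, 1]`, zero diagonal, asymmetries above `1e-9` rejected.
#'
#' @param path CSV file
#' @return a `pairwise_distance_matrix`
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("distance matrix CSV needs a label column", call. = FALSE)
  labels <- trimws(as.character(df[[1]]))
  body <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric entries in distance matrix", call. = FALSE)
  header <- trimws(colnames(df)[-1])
  if (nrow(body) != ncol(body)) {
    stop("distance matrix must be square, got ", nrow(body), "x", ncol(body),
         call. = FALSE)
  }
  if (!identical(labels, header)) {
    stop("row labels do not match column labels", call. = FALSE)
  }
  distance_matrix(body, labels)
}

#' Write a pairwise distance matrix as CSV
#'
#' @param dm a `pairwise_distance_matrix` (or labeled symmetric matrix)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- as_distance_input(dm)
  df <- data.frame(element = rownames(dm), dm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
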