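# Independent oracles: deliberately naive implementations that share no code
# with the package internals.

# recursive memoized evaluation of U(S) = max_i { U(S\i) + min dist(i, S\i) }
oracle_weitzman <- function(d) {
  d <- unclass(as.matrix(d))
  k <- nrow(d)
  memo <- rep(NA_real_, 2^k)
  rec <- function(mask) {
    if (!is.na(memo[mask + 1])) return(memo[mask + 1])
    bits <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) != 0L)
    val <- 0
    if (length(bits) >= 2) {
      val <- max(vapply(bits, function(i) {
        rest <- setdiff(bits, i)
        rec(mask - bitwShiftL(1L, i - 1L)) + min(d[i, rest])
      }, numeric(1)))
    }
    memo[mask + 1] <<- val
    val
  }
  rec(2^k - 1L)
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
oracle_apsp <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# distance histogram of one row of an all-pairs distance matrix
oracle_ndd_from_apsp <- function(dists, i) {
  n <- length(dists)
  di <- dists[-i]
  counts <- vapply(seq_len(n - 1), function(b) sum(di == b), numeric(1))
  c(counts, sum(is.infinite(di))) / (n - 1)
}

# direct textbook evaluation of the Jensen-Shannon divergence
oracle_js <- function(p, q) {
  h <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  }
  h((p + q) / 2) - (h(p) + h(q)) / 2
}

random_sym_matrix <- function(k, scale = 1) {
  m <- matrix(0, k, k, dimnames = list(letters[seq_len(k)], letters[seq_len(k)]))
  m[upper.tri(m)] <- stats::runif(k * (k - 1) / 2) * scale
  m + t(m)
}

random_distribution <- function(k) {
  x <- stats::rexp(k)
  zero <- stats::runif(k) < 0.3  # exercise empty outcomes
  x[zero] <- 0
  if (all(x == 0)) x[1] <- 1
  x / sum(x)
}
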