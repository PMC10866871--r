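# Internal helpers: canonical dyad indexing and reproducible seed streams.

#' Enumerate all dyads of an n-node universe
#'
#' Returns the canonical ordering of unordered node pairs used throughout the
#' package: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). Fold assignments,
#' oracle probability vectors and feature blocks computed "for all dyads" are
#' aligned to this order.
#'
#' @param n Number of nodes (>= 2).
#' @return Integer matrix with two columns `i` and `j`, `i < j`, and
#'   `choose(n, 2)` rows.
#' @export
allDyads <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Canonical linear index of a dyad
#'
#' Maps node pairs to their row in [allDyads()]. Inputs are vectorized and
#' unordered: `(i, j)` and `(j, i)` give the same index.
#'
#' @param i,j Node indices in `1..n` (`i != j`).
#' @param n Number of nodes.
#' @return Integer vector of indices into the canonical dyad order.
#' @export
dyadIndex <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  stopifnot(all(lo >= 1L), all(hi <= n), all(lo < hi))
  as.integer((lo - 1L) * (2L * n - lo) / 2L + (hi - lo))
}

# Dyad indices of the edges of an igraph layer (canonical order indices).
edgeDyadIndices <- function(g, n = igraph::vcount(g)) {
  if (igraph::ecount(g) == 0L) return(integer(0))
  el <- igraph::as_edgelist(g, names = FALSE)
  dyadIndex(el[, 1L], el[, 2L], n)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based seed splitting: one master seed deterministically yields k
# independent sub-seeds (all < 2^31 - 1). Used so that fold partition, each
# group's dyad sampling, and the classifier draw from independent streams.
deriveSeeds <- function(master, k) {
  withSeed(master, sample.int(2147483646L, k, replace = TRUE))
}
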