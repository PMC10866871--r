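# Data model and I/O for layered temporal networks.

#' Construct a TemporalNetwork
#'
#' Builds a temporal network either from a list of igraph layers (all on the
#' same `n` vertices) or from an edge table with columns `(layer, i, j)`
#' (1-based layers and nodes). Duplicate edges are collapsed, self-loops
#' dropped with a warning, and layers missing from the table become empty.
#'
#' @param layers List of undirected `igraph` objects, or a 3-column matrix /
#'   data frame of `(layer, i, j)` records.
#' @param n Node count; required for an edge table unless it can be taken as
#'   the maximum node id observed.
#' @param nLayers Optional layer count when building from an edge table
#'   (defaults to the maximum layer index observed).
#' @return A [TemporalNetwork-class].
#' @examples
#' el <- cbind(layer = c(1, 1, 2), i = c(1, 2, 1), j = c(2, 3, 2))
#' net <- temporalNetwork(el, n = 3)
#' nLayers(net)
#' @export
temporalNetwork <- function(layers, n = NULL, nLayers = NULL) {
  if (is.matrix(layers) || is.data.frame(layers)) {
    el <- as.matrix(layers)
    if (ncol(el) < 3L) stop("edge table must have columns (layer, i, j)")
    storage.mode(el) <- "double"
    if (anyNA(el)) stop("edge table contains missing values")
    if (any(el != floor(el))) stop("edge table entries must be integers")
    if (any(el < 1)) stop("layers and node ids must be >= 1")
    if (is.null(n)) n <- if (nrow(el)) max(el[, 2:3]) else
      stop("n is required for an empty edge table")
    if (any(el[, 2:3] > n)) stop("node id exceeds n")
    if (is.null(nLayers)) nLayers <- if (nrow(el)) max(el[, 1L]) else 1L
    n <- as.integer(n); nLayers <- as.integer(nLayers)
    loops <- el[, 2L] == el[, 3L]
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop record(s)", sum(loops)))
      el <- el[!loops, , drop = FALSE]
    }
    gl <- lapply(seq_len(nLayers), function(t) {
      rows <- el[el[, 1L] == t, 2:3, drop = FALSE]
      if (nrow(rows)) {
        idx <- unique(dyadIndex(rows[, 1L], rows[, 2L], n))
        d <- allDyads(n)[idx, , drop = FALSE]
        igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                          as.vector(t(d)))
      } else {
        igraph::make_empty_graph(n, directed = FALSE)
      }
    })
    methods::new("TemporalNetwork", n = n, layers = gl)
  } else {
    if (is.null(n)) {
      if (!length(layers)) stop("n is required for an empty layer list")
      n <- igraph::vcount(layers[[1L]])
    }
    layers <- lapply(layers, function(g)
      igraph::simplify(igraph::as_undirected(g, mode = "collapse")))
    methods::new("TemporalNetwork", n = as.integer(n), layers = layers)
  }
}

#' @rdname nNodes
#' @export
setMethod("nNodes", "TemporalNetwork", function(x) x@n)

#' @rdname nLayers
#' @export
setMethod("nLayers", "TemporalNetwork", function(x) length(x@layers))

#' @rdname getLayer
#' @export
setMethod("getLayer", "TemporalNetwork", function(x, t) {
  t <- as.integer(t)
  if (t < 1L || t > length(x@layers))
    stop(sprintf("layer index %d out of range 1..%d", t, length(x@layers)))
  x@layers[[t]]
})

setMethod("show", "TemporalNetwork", function(object) {
  m <- vapply(object@layers, igraph::ecount, numeric(1))
  cat(sprintf("TemporalNetwork: %d nodes, %d layers\n",
              object@n, length(object@layers)))
  cat("  edges per layer:", paste(m, collapse = " "), "\n")
})

#' Read a layered edge list
#'
#' Parses the 3-column whitespace/TSV dialect `(layer, u, v)` with 0-based
#' layer indices and node ids, `#` comment lines allowed. Duplicate records
#' collapse to a single edge, self-loops are dropped with a warning, and
#' layer indices missing from the file yield empty layers.
#'
#' @param source Path or connection.
#' @param n Optional node count; defaults to one more than the largest node
#'   id in the file.
#' @return A [TemporalNetwork-class].
#' @seealso [writeTemporalEdgelist()]
#' @export
readTemporalEdgelist <- function(source, n = NULL) {
  lines <- readLines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    stop(sprintf("parse error at line %d: fewer than 3 fields", lineno[bad[1L]]))
  rec <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[1:3]))
    v
  }, numeric(3))
  badnum <- which(apply(rec, 2L, function(v) anyNA(v) | any(v != floor(v))))
  if (length(badnum))
    stop(sprintf("parse error at line %d: non-integer field", lineno[badnum[1L]]))
  if (any(rec < 0)) stop("negative layer or node id")
  if (!length(lines)) {
    if (is.null(n)) stop("empty edge list and no n given")
    return(temporalNetwork(matrix(numeric(0), 0, 3), n = n, nLayers = 1L))
  }
  el <- t(rec)
  if (is.null(n)) n <- max(el[, 2:3]) + 1
  el[, 1L] <- el[, 1L] + 1           # 0-based on disk -> 1-based in R
  el[, 2:3] <- el[, 2:3] + 1
  temporalNetwork(el, n = n, nLayers = max(el[, 1L]))
}

#' Write a layered edge list
#'
#' Emits one `(layer, u, v)` record per edge per layer with `u < v`, sorted
#' by (layer, u, v), 0-based, tab-separated — the same dialect
#' [readTemporalEdgelist()] consumes, so the round trip is the identity.
#'
#' @param net A [TemporalNetwork-class].
#' @param sink Path or connection.
#' @return Invisibly, the number of records written.
#' @export
writeTemporalEdgelist <- function(net, sink) {
  recs <- lapply(seq_len(nLayers(net)), function(t) {
    g <- getLayer(net, t)
    if (igraph::ecount(g) == 0L) return(NULL)
    idx <- sort(edgeDyadIndices(g, net@n))
    d <- allDyads(net@n)[idx, , drop = FALSE]
    cbind(t - 1L, d[, 1L] - 1L, d[, 2L] - 1L)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) recs <- matrix(integer(0), 0, 3)
  utils::write.table(recs, sink, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(recs))
}

#' Intersection of consecutive layers
#'
#' The AND-aggregation over a window: the returned graph contains edge
#' `(i, j)` iff that edge is present in every one of the `q` layers
#' `tStart, ..., tStart + q - 1`. With `q = 1` this is the layer itself.
#' This is the aggregation underlying temporal common neighbors.
#'
#' @param net A [TemporalNetwork-class].
#' @param tStart First layer of the window (1-based).
#' @param q Window length (>= 1).
#' @return An `igraph` on the full node universe.
#' @seealso [temporalCommonNeighbors()]
#' @export
intersectionGraph <- function(net, tStart, q) {
  tStart <- as.integer(tStart); q <- as.integer(q)
  if (q < 1L || tStart < 1L || tStart + q - 1L > nLayers(net))
    stop(sprintf("window [%d, %d] out of range 1..%d",
                 tStart, tStart + q - 1L, nLayers(net)))
  idx <- edgeDyadIndices(getLayer(net, tStart), net@n)
  if (q > 1L) for (t in (tStart + 1L):(tStart + q - 1L))
    idx <- intersect(idx, edgeDyadIndices(getLayer(net, t), net@n))
  graphFromDyadIndices(idx, net@n)
}

# Build an igraph from canonical dyad indices.
graphFromDyadIndices <- function(idx, n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(idx)) {
    d <- allDyads(n)[idx, , drop = FALSE]
    g <- igraph::add_edges(g, as.vector(t(d)))
  }
  g
}
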