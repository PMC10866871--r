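# The per-layer bank of 41 static topological features.
#
# A layer's feature block has one row per dyad and exactly 41 columns:
#   5 global graph measures (constant down the rows),
#   8 dyadic similarity scores,
#   6 low-rank spectral scores from a truncated SVD of the adjacency matrix,
#   11 node-level centralities for each endpoint (i side then j side).
# Every entry is finite: vacuous definitions (clustering of a degree-<2
# node, closeness or neighbor degree of an isolate) are mapped to 0, and
# shortest-path distance of a disconnected dyad is capped at n.

.globalNames <- c("m", "density", "NT", "meanLCC", "ND")
.pairNames   <- c("CN", "JC", "AA", "RA", "PA", "LHN", "SP", "LP")
.lowrankNames <- c("LRA", "dLRA", "mLRA", "LRAapprox", "dLRAapprox", "mLRAapprox")
.nodeNames   <- c("DC", "EC", "KC", "PR", "BC", "CC", "LC", "AND", "LCC",
                  "coreNum", "triangles")

#' Canonical feature names
#'
#' The fixed, ordered list of the 41 per-layer feature columns, or the 30
#' base feature names (node features counted once, without the `_i`/`_j`
#' endpoint suffix) used for feature subsetting and importance aggregation.
#'
#' Acronyms follow common usage: CN common neighbors, JC Jaccard, AA
#' Adamic-Adar, RA resource allocation, PA preferential attachment, LHN
#' Leicht-Holme-Newman, SP shortest path, LP local path index, LRA/dLRA/mLRA
#' low-rank approximation scores (`*approx` = negative entries of the
#' reconstruction clipped to 0), DC degree centrality, EC eigenvector, KC
#' Katz, PR PageRank, BC betweenness, CC closeness, LC load centrality, AND
#' average neighbor degree, LCC local clustering, NT network transitivity,
#' ND network diameter.
#'
#' @param base If `TRUE`, return the 30 base names instead of the 41
#'   column names.
#' @return Character vector of length 41 (or 30).
#' @export
featureNames <- function(base = FALSE) {
  if (base)
    c(.globalNames, .pairNames, .lowrankNames, .nodeNames)
  else
    c(.globalNames, .pairNames, .lowrankNames,
      paste0(.nodeNames, "_i"), paste0(.nodeNames, "_j"))
}

# Base feature of each of the 41 columns (strips the endpoint suffix).
featureBase <- function(cols = featureNames()) sub("_[ij]$", "", cols)

#' Global features of one layer
#'
#' Edge count, density, transitivity, mean local clustering coefficient, and
#' the diameter of the largest connected component (0 for an edgeless
#' graph). These enter every dyad's feature vector unchanged.
#'
#' @param g Simple undirected `igraph`.
#' @return Named numeric vector of length 5.
#' @export
globalFeatures <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  dens <- if (n >= 2L) m / choose(n, 2) else 0
  nt <- igraph::transitivity(g, type = "global")
  if (is.nan(nt)) nt <- 0
  lcc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mlcc <- if (n) mean(lcc) else 0
  nd <- 0
  if (m > 0L) {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    nd <- igraph::diameter(sub, unconnected = FALSE)
  }
  c(m = m, density = dens, NT = nt, meanLCC = mlcc, ND = nd)
}

# Load centrality (Newman's flow-splitting betweenness variant): for each
# source, one unit of "load" starts at every reachable node and flows back
# toward the source, splitting equally over the shortest-path predecessors
# at each step. Normalized by (n-1)(n-2) like betweenness.
loadCentrality <- function(g) {
  n <- igraph::vcount(g)
  load <- numeric(n)
  if (igraph::ecount(g) == 0L || n <= 2L) return(load)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  for (s in seq_len(n)) {
    dist <- rep.int(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    order <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- dist[frontier[1L]] + 1L
      order <- c(order, nxt)
      frontier <- nxt
    }
    reach <- order
    between <- rep.int(1, n)
    for (v in rev(reach)) {
      if (dist[v] <= 1L) next   # predecessors are the source only
      nb <- adj[[v]]
      preds <- nb[!is.na(dist[nb]) & dist[nb] == dist[v] - 1L]
      share <- between[v] / length(preds)
      between[preds] <- between[preds] + share
    }
    between[reach] <- between[reach] - 1
    load[reach] <- load[reach] + between[reach]
  }
  load / ((n - 1) * (n - 2))
}

#' Node-level features of one layer
#'
#' Eleven per-node measures: degree centrality, eigenvector centrality
#' (principal eigenvector of the adjacency matrix, scaled to maximum 1),
#' Katz centrality with attenuation `0.9 / lambda_max` (computed by a direct
#' linear solve), PageRank (damping 0.85; isolated nodes get 0 and the
#' remainder renormalizes over non-isolates), normalized betweenness,
#' normalized closeness, load centrality, average neighbor degree, local
#' clustering coefficient, k-core number, and triangle count. On an
#' edgeless graph every column is 0.
#'
#' @param g Simple undirected `igraph`.
#' @return `n x 11` numeric matrix with columns `DC, EC, KC, PR, BC, CC,
#'   LC, AND, LCC, coreNum, triangles`.
#' @export
nodeFeatures <- function(g) {
  n <- igraph::vcount(g)
  out <- matrix(0, n, length(.nodeNames),
                dimnames = list(NULL, .nodeNames))
  if (igraph::ecount(g) == 0L) return(out)
  deg <- igraph::degree(g)
  out[, "DC"] <- if (n > 1L) deg / (n - 1) else 0
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  es <- tryCatch(eigen(A, symmetric = TRUE),
                 error = function(e) stop("eigenvector centrality failed: ",
                                          conditionMessage(e)))
  v <- es$vectors[, 1L]
  v <- v * sign(v[which.max(abs(v))])
  v[v < 0] <- 0
  if (max(v) > 0) v <- v / max(v)
  out[, "EC"] <- v
  lam <- es$values[1L]
  if (lam > 0) {
    alpha <- 0.9 / lam
    kc <- tryCatch(solve(diag(n) - alpha * A, rep(1, n)) - 1,
                   error = function(e) stop("Katz centrality failed: ",
                                            conditionMessage(e)))
    out[, "KC"] <- kc
  }
  iso <- deg == 0L
  if (any(!iso)) {
    sub <- igraph::induced_subgraph(g, which(!iso))
    pr <- igraph::page_rank(sub, damping = 0.85)$vector
    out[!iso, "PR"] <- pr
  }
  out[, "BC"] <- igraph::betweenness(g, normalized = TRUE)
  cc <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cc[!is.finite(cc)] <- 0
  out[, "CC"] <- cc
  out[, "LC"] <- loadCentrality(g)
  knn <- suppressWarnings(igraph::knn(g)$knn)
  knn[!is.finite(knn)] <- 0
  out[, "AND"] <- knn
  out[, "LCC"] <- igraph::transitivity(g, type = "local", isolates = "zero")
  out[, "coreNum"] <- igraph::coreness(g)
  out[, "triangles"] <- igraph::count_triangles(g)
  out
}

#' Dyadic similarity features
#'
#' For each requested dyad: common neighbors, Jaccard coefficient,
#' Adamic-Adar, resource allocation, preferential attachment (raw degree
#' product), Leicht-Holme-Newman (CN / PA), shortest-path distance (capped
#' at `n` for disconnected dyads), and the local path index
#' `(A^2)_{ij} + eps (A^3)_{ij}`.
#'
#' @param g Simple undirected `igraph`.
#' @param dyads Integer matrix (i, j) of node pairs, `i != j`.
#' @param lpEps Damping of the cubic term in the local path index.
#' @return `nrow(dyads) x 8` numeric matrix.
#' @export
pairwiseFeatures <- function(g, dyads, lpEps = 0.01) {
  n <- igraph::vcount(g)
  stopifnot(all(dyads[, 1L] != dyads[, 2L]))
  idx <- cbind(dyads[, 1L], dyads[, 2L])
  out <- matrix(0, nrow(dyads), length(.pairNames),
                dimnames = list(NULL, .pairNames))
  deg <- igraph::degree(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  A2 <- A %*% A
  A3 <- A2 %*% A
  cn <- A2[idx]
  uni <- deg[idx[, 1L]] + deg[idx[, 2L]] - cn
  pa <- deg[idx[, 1L]] * deg[idx[, 2L]]
  invlog <- ifelse(deg > 1, 1 / log(deg), 0)
  invdeg <- ifelse(deg > 0, 1 / deg, 0)
  out[, "CN"] <- cn
  out[, "JC"] <- ifelse(uni > 0, cn / uni, 0)
  out[, "AA"] <- (A %*% (invlog * A))[idx]
  out[, "RA"] <- (A %*% (invdeg * A))[idx]
  out[, "PA"] <- pa
  out[, "LHN"] <- ifelse(pa > 0, cn / pa, 0)
  sp <- igraph::distances(g)[idx]
  sp[!is.finite(sp)] <- n
  out[, "SP"] <- sp
  out[, "LP"] <- cn + lpEps * A3[idx]
  out
}

#' Low-rank spectral features
#'
#' From the rank-`r` truncated SVD reconstruction `Ahat` of the adjacency
#' matrix: the reconstructed entry `Ahat[i, j]` (LRA), the dot product of
#' columns `i` and `j` (dLRA), and the mean of the reconstruction entries
#' linking the combined neighborhood of `i` and `j` back to the two
#' endpoints (mLRA); plus the same three scores computed after clipping
#' negative reconstruction entries to 0 (`*approx`).
#'
#' @param g Simple undirected `igraph`.
#' @param dyads Integer matrix (i, j) of node pairs.
#' @param r Truncation rank in `1..n-1`; `NULL` means `min(16, n - 1)`.
#' @return `nrow(dyads) x 6` numeric matrix.
#' @export
lowRankFeatures <- function(g, dyads, r = NULL) {
  n <- igraph::vcount(g)
  if (is.null(r)) r <- min(16L, n - 1L)
  r <- as.integer(r)
  if (r < 1L || r > n - 1L) stop(sprintf("rank %d out of range 1..%d", r, n - 1L))
  out <- matrix(0, nrow(dyads), length(.lowrankNames),
                dimnames = list(NULL, .lowrankNames))
  if (igraph::ecount(g) == 0L) return(out)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  sv <- svd(A, nu = r, nv = r)
  Ahat <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
  scores <- function(Ah) {
    idx <- cbind(dyads[, 1L], dyads[, 2L])
    lra <- Ah[idx]
    Gm <- crossprod(Ah)
    dlra <- Gm[idx]
    nbr <- (A[dyads[, 1L], , drop = FALSE] +
            A[dyads[, 2L], , drop = FALSE]) > 0
    cnt <- rowSums(nbr)
    S <- nbr %*% Ah
    si <- S[cbind(seq_len(nrow(dyads)), dyads[, 1L])]
    sj <- S[cbind(seq_len(nrow(dyads)), dyads[, 2L])]
    mlra <- ifelse(cnt > 0, (si + sj) / (2 * cnt), 0)
    cbind(lra, dlra, mlra)
  }
  out[, 1:3] <- scores(Ahat)
  out[, 4:6] <- scores(pmax(Ahat, 0))
  out
}

#' Assemble the 41-column feature block of one layer
#'
#' Concatenates the global, dyadic, low-rank, and endpoint node features in
#' the canonical order of [featureNames()] for the requested dyads (all
#' dyads of the node universe by default).
#'
#' @param g Simple undirected `igraph`.
#' @param dyads Integer matrix (i, j); `NULL` means all `choose(n, 2)`
#'   dyads in canonical order.
#' @param r Low-rank truncation rank (see [lowRankFeatures()]).
#' @param lpEps Local path damping (see [pairwiseFeatures()]).
#' @param cols Columns to return, a subset of [featureNames()] (default
#'   all 41). Feature groups with no requested column are skipped, so a
#'   restricted stacker (say, common neighbors only) avoids the expensive
#'   centrality and SVD computations.
#' @return Numeric matrix `nrow(dyads) x length(cols)` with the dyad
#'   matrix attached as attribute `"dyads"`.
#' @export
layerFeatureBlock <- function(g, dyads = NULL, r = NULL, lpEps = 0.01,
                              cols = featureNames()) {
  n <- igraph::vcount(g)
  if (is.null(dyads)) dyads <- allDyads(n)
  dyads <- matrix(as.integer(dyads), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  nd <- nrow(dyads)
  stopifnot(all(cols %in% featureNames()))
  parts <- list()
  if (any(cols %in% .globalNames)) {
    glob <- globalFeatures(g)
    parts$glob <- matrix(rep(glob, each = nd), nd, 5L,
                         dimnames = list(NULL, .globalNames))
  }
  if (any(cols %in% .pairNames))
    parts$pair <- if (nd) pairwiseFeatures(g, dyads, lpEps = lpEps) else
      matrix(0, 0L, length(.pairNames), dimnames = list(NULL, .pairNames))
  if (any(cols %in% .lowrankNames))
    parts$lowrank <- if (nd) lowRankFeatures(g, dyads, r = r) else
      matrix(0, 0L, length(.lowrankNames),
             dimnames = list(NULL, .lowrankNames))
  nodeCols <- intersect(featureBase(cols), .nodeNames)
  if (length(nodeCols)) {
    node <- nodeFeatures(g)
    ni <- node[dyads[, 1L], , drop = FALSE]
    nj <- node[dyads[, 2L], , drop = FALSE]
    colnames(ni) <- paste0(.nodeNames, "_i")
    colnames(nj) <- paste0(.nodeNames, "_j")
    parts$ni <- ni
    parts$nj <- nj
  }
  X <- do.call(cbind, parts)
  X <- X[, cols, drop = FALSE]
  attr(X, "dyads") <- dyads
  X
}
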