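# Independent brute-force oracles used to check the package's vectorized
# implementations on small instances, plus fixture generators.

library(igraph)

# Random Erdos-Renyi temporal network with i.i.d. layers.
makeErdosNet <- function(n, T, p, seed) {
  set.seed(seed)
  layers <- lapply(seq_len(T), function(t)
    igraph::sample_gnp(n, p, directed = FALSE))
  temporalNetwork(layers, n = n)
}

graphFromEdges0 <- function(n, edges0) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges0)) g <- igraph::add_edges(g, as.vector(t(edges0)) + 1L)
  g
}

edgeSet <- function(g) {
  if (igraph::ecount(g) == 0L) return(character(0))
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}

# O(P*N) pairwise AUC.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (s in pos) tot <- tot + sum(s > neg) + 0.5 * sum(s == neg)
  tot / (length(pos) * length(neg))
}

# Average precision by exhaustive threshold enumeration.
bruteAP <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prevRecall <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + (rec - prevRecall) * prec
    prevRecall <- rec
  }
  ap
}

# Expected oracle AUC by O(D^2) enumeration over ordered dyad pairs
# (including d == d'), ties counted one half.
bruteExpectedOracleAUC <- function(P) {
  num <- 0
  for (d in seq_along(P)) for (dp in seq_along(P)) {
    w <- P[d] * (1 - P[dp])
    if (P[d] > P[dp]) num <- num + w
    else if (P[d] == P[dp]) num <- num + w / 2
  }
  num / (sum(P) * sum(1 - P))
}

# Per-definition dyadic similarity scores via explicit neighborhood sets.
brutePairwise <- function(g, i, j) {
  n <- igraph::vcount(g)
  Ni <- as.integer(igraph::neighbors(g, i))
  Nj <- as.integer(igraph::neighbors(g, j))
  cn <- intersect(Ni, Nj)
  deg <- igraph::degree(g)
  sp <- suppressWarnings(igraph::distances(g, v = i, to = j)[1, 1])
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  A2 <- A %*% A; A3 <- A2 %*% A
  c(CN = length(cn),
    JC = if (length(union(Ni, Nj))) length(cn) / length(union(Ni, Nj)) else 0,
    AA = sum(1 / log(deg[cn])),
    RA = sum(1 / deg[cn]),
    PA = deg[i] * deg[j],
    LHN = if (deg[i] * deg[j] > 0) length(cn) / (deg[i] * deg[j]) else 0,
    SP = if (is.finite(sp)) sp else n,
    LP = A2[i, j] + 0.01 * A3[i, j])
}

# Power-iteration eigenvector centrality scaled to max 1.
powerIterationEC <- function(A, tol = 1e-12, maxit = 10000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(maxit)) {
    y <- as.vector(A %*% x)
    if (max(abs(y)) == 0) return(rep(0, n))
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) break
    x <- y
  }
  y[y < 0] <- 0
  y / max(y)
}

# Global features recomputed from first principles.
bruteGlobal <- function(g) {
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  tri <- diag(A %*% A %*% A)           # 2 * triangles through each node
  paths <- colSums(A) * (colSums(A) - 1) # ordered connected triples centred
  nt <- if (sum(paths) > 0) sum(tri) / sum(paths) else 0
  lcc <- ifelse(paths > 0, tri / paths, 0)
  D <- igraph::distances(g)
  comp <- igraph::components(g)
  nd <- 0
  if (m > 0) {
    big <- which(comp$membership == which.max(comp$csize))
    nd <- max(D[big, big])
  }
  c(m = m, density = m / choose(n, 2), NT = nt, meanLCC = mean(lcc), ND = nd)
}

# Dense rank-r SVD reconstruction, scored per definition with loops.
bruteLowRank <- function(g, r, i, j) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  s <- svd(A)
  Ah <- s$u[, 1:r, drop = FALSE] %*% diag(s$d[1:r], r) %*%
    t(s$v[, 1:r, drop = FALSE])
  one <- function(Ah) {
    nbrs <- union(as.integer(igraph::neighbors(g, i)), as.integer(igraph::neighbors(g, j)))
    ml <- if (length(nbrs)) mean(c(Ah[nbrs, i], Ah[nbrs, j])) else 0
    c(Ah[i, j], sum(Ah[, i] * Ah[, j]), ml)
  }
  c(one(Ah), one(pmax(Ah, 0)))
}

# Triple-loop temporal common neighbors.
bruteTCN <- function(net, t, q, i, j) {
  n <- nNodes(net)
  count <- 0
  for (w in seq_len(n)) {
    if (w == i || w == j) next
    ok <- TRUE
    for (s in (t - q):(t - 1)) {
      g <- getLayer(net, s)
      if (!igraph::are_adjacent(g, i, w) || !igraph::are_adjacent(g, j, w)) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1
  }
  count
}
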