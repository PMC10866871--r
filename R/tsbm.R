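# Degree-corrected temporal stochastic block models and oracle AUC bounds.

#' Create T-SBM parameters
#'
#' @param variant `"community_label"` (labels re-drawn each layer, copied
#'   with probability `p`) or `"edge_correlated"` (fixed labels, dyad edge
#'   states copied with probability `p`).
#' @param n,layers Nodes and layer count (defaults match the synthetic
#'   study design: 200 nodes, 10 layers).
#' @param k Number of communities.
#' @param p Temporal dependency (copy probability).
#' @param mu Fraction of uniformly random edges on top of the block
#'   structure.
#' @param c Target mean degree (default 10).
#' @param theta Optional per-node degree propensities (mean 1). When `NULL`
#'   and `thetaHet = TRUE`, [generateTSBM()] draws them uniformly on
#'   \[0.5, 1.5\] and normalizes to mean 1; with `thetaHet = FALSE` they
#'   are identically 1.
#' @param thetaHet Logical, degree heterogeneity on/off.
#' @return A [TSBMParams-class].
#' @export
tsbmParams <- function(variant = c("community_label", "edge_correlated"),
                       n = 200L, layers = 10L, k = 5L, p = 0.8, mu = 0.1,
                       c = 10, theta = NULL, thetaHet = TRUE) {
  variant <- match.arg(variant)
  if (is.null(theta) && !thetaHet) theta <- rep(1, n)
  methods::new("TSBMParams",
    n = as.integer(n), layers = as.integer(layers), k = as.integer(k),
    p = as.numeric(p), mu = as.numeric(mu), c = as.numeric(c),
    theta = if (is.null(theta)) numeric(0) else as.numeric(theta),
    thetaHet = isTRUE(thetaHet), variant = variant)
}

setMethod("show", "TSBMParams", function(object) {
  cat(sprintf("TSBMParams (%s): n=%d, %d layers, k=%d, p=%.2f, mu=%.2f, c=%g, theta %s\n",
              object@variant, object@n, object@layers, object@k, object@p,
              object@mu, object@c,
              if (!length(object@theta)) "to be drawn"
              else if (object@thetaHet) "heterogeneous" else "constant"))
})

.thetaOrStop <- function(params) {
  if (!length(params@theta))
    stop("theta has not been drawn yet; generate a realization first or ",
         "supply theta explicitly")
  params@theta
}

#' Degree-corrected planted-partition connection probability
#'
#' \eqn{P_{ij} = \min\{1, \theta_i\theta_j (c/n)[(1-\mu)k\delta_{g_ig_j} + \mu]\}}.
#' With equal-sized random communities the expected mean degree is `c`
#' whenever the cap is inactive, independent of `mu` and `k`. `k = 1` or
#' `mu = 1` reduce to a pure degree-corrected random graph.
#'
#' @param params A [TSBMParams-class] with concrete `theta`.
#' @param labels Integer community labels in `1..k` for all `n` nodes.
#' @param i,j Optional node index vectors; if given, the probabilities of
#'   the dyads `(i, j)` are returned, otherwise the full `n x n` matrix
#'   (diagonal set to 0).
#' @return Numeric vector or matrix of probabilities.
#' @export
blockProbability <- function(params, labels, i = NULL, j = NULL) {
  theta <- .thetaOrStop(params)
  n <- params@n
  stopifnot(length(labels) == n, all(labels >= 1L), all(labels <= params@k))
  if (!is.null(i)) {
    stopifnot(!is.null(j), length(i) == length(j))
    same <- labels[i] == labels[j]
    return(pmin(1, theta[i] * theta[j] * (params@c / n) *
                  ((1 - params@mu) * params@k * same + params@mu)))
  }
  same <- outer(labels, labels, "==")
  P <- pmin(outer(theta, theta) * (params@c / n) *
              ((1 - params@mu) * params@k * same + params@mu), 1)
  diag(P) <- 0
  P
}

# Block probabilities over the canonical dyad order.
blockProbabilityVec <- function(params, labels) {
  d <- allDyads(params@n)
  blockProbability(params, labels, d[, 1L], d[, 2L])
}

#' Simulate a temporal stochastic block model
#'
#' Community-label variant: the first layer's labels are uniform over the
#' `k` communities; in each later layer every node independently keeps its
#' label with probability `p` and otherwise re-draws it uniformly. Each
#' layer's edges are independent Bernoulli draws from the block
#' probabilities under that layer's labels.
#'
#' Edge-correlated variant: labels are drawn once and never change; the
#' first layer is a Bernoulli draw from the block probabilities, and in
#' each later layer every dyad independently keeps its previous edge state
#' with probability `p` and otherwise re-draws it from its block
#' probability — so the marginal edge probability of every dyad is
#' stationary across layers.
#'
#' @param params A [TSBMParams-class]. If `theta` is empty it is drawn
#'   first (uniform on \[0.5, 1.5\], normalized to mean 1).
#' @param seed Seed for the realization.
#' @return A [TSBMRealization-class] holding the network, the latent label
#'   table (one row per layer, or a single row for the edge-correlated
#'   variant) and the concrete parameters.
#' @export
generateTSBM <- function(params, seed) {
  withSeed(seed, {
    if (!length(params@theta)) {
      th <- stats::runif(params@n, 0.5, 1.5)
      params@theta <- th / mean(th)
    }
    n <- params@n
    T <- params@layers
    d <- allDyads(n)
    D <- nrow(d)
    if (params@variant == "community_label") {
      labels <- matrix(0L, T, n)
      labels[1L, ] <- sample.int(params@k, n, replace = TRUE)
      for (t in seq_len(T)[-1L]) {
        keep <- stats::runif(n) < params@p
        labels[t, ] <- ifelse(keep, labels[t - 1L, ],
                              sample.int(params@k, n, replace = TRUE))
      }
      gl <- lapply(seq_len(T), function(t) {
        P <- blockProbabilityVec(params, labels[t, ])
        graphFromDyadIndices(which(stats::runif(D) < P), n)
      })
    } else {
      lab <- sample.int(params@k, n, replace = TRUE)
      labels <- matrix(lab, 1L, n)
      P <- blockProbabilityVec(params, lab)
      state <- stats::runif(D) < P
      gl <- vector("list", T)
      gl[[1L]] <- graphFromDyadIndices(which(state), n)
      for (t in seq_len(T)[-1L]) {
        keep <- stats::runif(D) < params@p
        redraw <- stats::runif(D) < P
        state <- ifelse(keep, state, redraw)
        gl[[t]] <- graphFromDyadIndices(which(state), n)
      }
    }
    methods::new("TSBMRealization",
      net = methods::new("TemporalNetwork", n = n, layers = gl),
      labels = labels, params = params)
  })
}

setMethod("show", "TSBMRealization", function(object) {
  cat("TSBMRealization of "); methods::show(object@params)
  methods::show(object@net)
})

#' Ground-truth oracle scores for a layer
#'
#' Scores every dyad with its true connection probability conditioned on
#' the realized latent state: the layer's community labels
#' (community-label variant) or the previous layer's adjacency combined
#' with the copy rule, `p * A[t-1] + (1 - p) * P_block` (edge-correlated
#' variant). These probabilities upper-bound every predictor's expected
#' AUC.
#'
#' @param real A [TSBMRealization-class].
#' @param t Layer to score (default: the last, i.e. the target layer).
#' @return An [OracleScores-class] over the canonical dyad order.
#' @export
oracleScores <- function(real, t = nLayers(real@net)) {
  params <- real@params
  t <- as.integer(t)
  if (params@variant == "community_label") {
    if (t > nrow(real@labels)) stop("no labels for layer ", t)
    probs <- blockProbabilityVec(params, real@labels[t, ])
    cond <- sprintf("community labels of layer %d", t)
  } else {
    if (t < 2L) stop("edge-correlated oracle needs a previous layer")
    prev <- logical(choose(params@n, 2))
    prev[edgeDyadIndices(getLayer(real@net, t - 1L), params@n)] <- TRUE
    P <- blockProbabilityVec(params, real@labels[1L, ])
    probs <- params@p * prev + (1 - params@p) * P
    cond <- sprintf("adjacency of layer %d", t - 1L)
  }
  methods::new("OracleScores", probs = probs, conditioning = cond,
               n = params@n)
}

#' @rdname oracleProbs
#' @export
setMethod("oracleProbs", "OracleScores", function(x) x@probs)

setMethod("show", "OracleScores", function(object) {
  cat(sprintf("OracleScores: %d dyads, conditioned on %s\n",
              length(object@probs), object@conditioning))
})

#' Expected oracle AUC by exact dyad enumeration
#'
#' The expected AUC of scoring dyads by their true connection
#' probabilities, enumerated exactly over all (ordered) dyad pairs:
#' \deqn{\frac{\sum_{d,d'} P_d (1 - P_{d'})
#'   [\mathbf{1}(P_d > P_{d'}) + \tfrac12 \mathbf{1}(P_d = P_{d'})]}
#'   {\sum_d P_d \sum_{d'} (1 - P_{d'})}.}
#' Computed by sorting and cumulative sums, so it is exact and fast even
#' for all `choose(n, 2)` dyads. If all probabilities are equal the value
#' is 0.5.
#'
#' @param probs An [OracleScores-class] or a numeric probability vector.
#' @return Expected AUC in `[0, 1]`.
#' @export
expectedOracleAUC <- function(probs) {
  if (methods::is(probs, "OracleScores")) probs <- probs@probs
  stopifnot(all(probs >= 0 & probs <= 1))
  sumP <- sum(probs)
  sumQ <- sum(1 - probs)
  if (sumP == 0 || sumQ == 0)
    stop("degenerate probabilities: one class has zero expected mass")
  vals <- sort(unique(probs))
  grp <- match(probs, vals)
  wP <- vapply(split(probs, grp), sum, numeric(1))
  wQ <- vapply(split(1 - probs, grp), sum, numeric(1))
  cumQbelow <- c(0, cumsum(wQ))[seq_along(wQ)]
  num <- sum(wP * cumQbelow) + 0.5 * sum(wP * wQ)
  num / (sumP * sumQ)
}

#' Empirical AUC of the oracle on a realized test set
#'
#' @param oracle An [OracleScores-class].
#' @param target `igraph` of the realized target layer (supplies labels).
#' @param dyadIdx Canonical dyad indices of the test set.
#' @return AUC of the oracle probabilities against the realized labels.
#' @export
oracleAUC <- function(oracle, target, dyadIdx) {
  n <- oracle@n
  isEdge <- logical(choose(n, 2))
  isEdge[edgeDyadIndices(target, n)] <- TRUE
  aucScore(oracle@probs[dyadIdx], as.integer(isEdge[dyadIdx]))
}

#' The synthetic parameter grid
#'
#' The 45-point Cartesian grid per simulator variant used in the synthetic
#' study: `p` in {0.9, 0.8, 0.7} (community-label) or {0.8, 0.7, 0.6}
#' (edge-correlated), `mu` in {0.1, 0.2, 0.3}, `k` in {1, 2, 5, 10, 15},
#' each with 200 nodes, 10 layers, and mean degree 10.
#'
#' @param variant `"community_label"` or `"edge_correlated"`.
#' @param n,layers,c Overrides for node count, layer count and mean degree
#'   (the defaults are the study values).
#' @return List of 45 [TSBMParams-class] objects.
#' @export
parameterGrid <- function(variant = c("community_label", "edge_correlated"),
                          n = 200L, layers = 10L, c = 10) {
  variant <- match.arg(variant)
  ps <- if (variant == "community_label") c(0.9, 0.8, 0.7) else c(0.8, 0.7, 0.6)
  grid <- expand.grid(p = ps, mu = c(0.1, 0.2, 0.3), k = c(1L, 2L, 5L, 10L, 15L))
  lapply(seq_len(nrow(grid)), function(r)
    tsbmParams(variant, n = n, layers = layers, k = grid$k[r],
               p = grid$p[r], mu = grid$mu[r], c = c))
}

#' Oracle as an ensemble provider / scorer
#'
#' Wraps a realization's oracle into the provider signature used by
#' [runSequentialStacking()]: for any label layer it returns the true
#' connection probabilities of the requested dyads. Useful as an unbeatable
#' reference scorer and for oracle-dominance checks.
#'
#' @param real A [TSBMRealization-class].
#' @return A function `f(net, cfg, dyads, labelLayer, observed)`.
#' @export
makeOracleProvider <- function(real) {
  function(net, cfg, dyads, labelLayer, observed = NULL) {
    sc <- oracleScores(real, labelLayer)
    sc@probs[dyadIndex(dyads[, 1L], dyads[, 2L], real@params@n)]
  }
}
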