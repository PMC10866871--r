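# Interpretable comparators: temporal common neighbors and per-feature
# time-series forecasting.

#' Temporal common neighbors
#'
#' Node `w` is a temporal common neighbor of a dyad `(i, j)` for target
#' layer `t` if `w` is adjacent to both `i` and `j` in every one of the `q`
#' layers preceding `t` — i.e. the common-neighbor count in the
#' intersection graph of that window. With `q = 1` this reduces exactly to
#' the static CN feature of layer `t - 1`.
#'
#' @param net A [TemporalNetwork-class].
#' @param t Target layer index (1-based); requires `t > q`.
#' @param q Number of prior layers that must all contain the edges.
#' @param dyads Integer matrix (i, j) of node pairs to score.
#' @return Numeric vector of counts, one per dyad.
#' @export
temporalCommonNeighbors <- function(net, t, q, dyads) {
  t <- as.integer(t); q <- as.integer(q)
  if (t - q < 1L) stop("window extends before the first layer")
  g <- intersectionGraph(net, t - q, q)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  (A %*% A)[cbind(dyads[, 1L], dyads[, 2L])]
}

#' Temporal common neighbors as an ensemble provider
#'
#' @return A provider function for [runSequentialStacking()] that scores
#'   dyads by [temporalCommonNeighbors()] over the `q` layers preceding
#'   each label layer.
#' @export
tcnProvider <- function() {
  function(net, cfg, dyads, labelLayer, observed = NULL) {
    temporalCommonNeighbors(net, labelLayer, cfg@q, dyads)
  }
}

# One-step forecast of a single series (general ARIMA order) with mean
# fallback. Differencing is handled explicitly so that, e.g., order
# (0, 1, 0) forecasts last value + mean step.
.forecastOne <- function(x, order) {
  if (all(x == x[1L])) return(x[1L])
  d <- order[2L]
  y <- x
  tails <- numeric(0)
  if (d > 0L) for (k in seq_len(d)) {
    tails <- c(tails, y[length(y)])
    y <- diff(y)
  }
  f <- if (all(y == y[1L])) {
    y[1L]
  } else if (order[1L] == 1L && d == 0L && order[3L] == 0L) {
    forecastAR1(matrix(y, 1L))
  } else {
    fit <- tryCatch(
      stats::arima(y, order = c(order[1L], 0L, order[3L]),
                   include.mean = TRUE, method = "CSS-ML"),
      error = function(e) NULL)
    if (is.null(fit)) mean(y) else as.numeric(stats::predict(fit, 1L)$pred)
  }
  if (d > 0L) for (k in rev(seq_len(d))) f <- tails[k] + f
  f
}

# Vectorized AR(1) one-step forecast by conditional least squares:
# regress x_t on x_{t-1}; forecast a + b * x_T. Degenerate regressors fall
# back to the series mean. S is nSeries x len.
forecastAR1 <- function(S) {
  len <- ncol(S)
  XL <- S[, -len, drop = FALSE]
  XN <- S[, -1L, drop = FALSE]
  ml <- rowMeans(XL)
  mn <- rowMeans(XN)
  den <- rowSums((XL - ml)^2)
  num <- rowSums((XL - ml) * (XN - mn))
  b <- ifelse(den > 0, num / den, 0)
  f <- ifelse(den > 0, mn + b * (S[, len] - ml), rowMeans(S))
  const <- matrixStats_allEqual(S)
  f[const] <- S[const, 1L]
  f
}

matrixStats_allEqual <- function(S) {
  rowSums(S != S[, 1L]) == 0L
}

#' One-step feature forecasts
#'
#' Forecasts each feature series one step ahead with an ARIMA model of the
#' given order. Constant series return their constant; a failed fit falls
#' back to the series mean, so every forecast is finite. The default order
#' (1, 0, 0) uses a fast closed-form conditional-least-squares AR(1) fit,
#' vectorized across series.
#'
#' @param history Numeric matrix, one row per series (e.g. one per
#'   dyad-feature pair), columns = consecutive layers, at least 3.
#' @param order ARIMA order `c(p, d, q)`.
#' @return Numeric vector of one-step forecasts, one per row.
#' @export
forecastFeatures <- function(history, order = c(1L, 0L, 0L)) {
  history <- rbind(history)
  if (ncol(history) < 3L) stop("need at least 3 observations per series")
  if (any(!is.finite(history))) stop("history must be finite")
  order <- as.integer(order)
  if (identical(order, c(1L, 0L, 0L))) {
    f <- forecastAR1(history)
    bad <- !is.finite(f)
    if (any(bad)) f[bad] <- rowMeans(history)[bad]
    return(f)
  }
  vapply(seq_len(nrow(history)), function(r)
    .forecastOne(history[r, ], order), numeric(1))
}

# Forecast feature matrix for one label layer: for each requested dyad, the
# 41 features are forecast one step ahead from their per-layer series over
# the (at most u) layers preceding the label layer.
forecastBlock <- function(net, cfg, labelLayer, dyadIdx, cache,
                          order = c(1L, 0L, 0L)) {
  from <- max(1L, labelLayer - cfg@u)
  win <- from:(labelLayer - 1L)
  if (length(win) < 3L) stop("need at least 3 prior layers to forecast")
  cols <- selectedColumns(cfg)
  ud <- sort(unique(dyadIdx))
  blocks <- lapply(win, function(t)
    cachedLayerBlock(net, t, cfg, cache)[ud, , drop = FALSE])
  out <- matrix(0, length(ud), length(cols),
                dimnames = list(NULL, paste0(cols, "_fc")))
  for (ci in seq_along(cols)) {
    S <- do.call(cbind, lapply(blocks, function(b) b[, ci]))
    out[, ci] <- forecastFeatures(S, order = order)
  }
  out[match(dyadIdx, ud), , drop = FALSE]
}

#' Time-series forecasting link predictor
#'
#' The ARIMA-based comparator: every one of the 41 per-layer features is
#' forecast one step ahead for each dyad, the forecast vectors of the
#' training groups (label layers as in [buildTrainingDesign()]) are used to
#' train the same random forest, and the target layer's forecast vectors
#' are scored. In the partially observed setting the observed target
#' layer's actual features are appended to the forecasts.
#'
#' @param net A [TemporalNetwork-class].
#' @param cfg A [StackingConfig-class].
#' @param foldAssignment Fold id per canonical dyad.
#' @param testFold Held-out fold.
#' @param dyads Integer matrix (i, j) of test dyads to score.
#' @param seed Seed (defaults to `cfg@seed`).
#' @param order ARIMA order.
#' @param cache Optional layer-block cache environment.
#' @return Numeric score per row of `dyads`.
#' @export
timeseriesPredictor <- function(net, cfg, foldAssignment, testFold, dyads,
                                seed = cfg@seed, order = c(1L, 0L, 0L),
                                cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  trainIdx <- which(foldAssignment != testFold)
  labelLayers <- trainingLabelLayers(net, cfg)
  partial <- cfg@setting == "partially_observed"
  if (partial) labelLayers <- c(labelLayers, nLayers(net))
  seeds <- deriveSeeds(seed, length(labelLayers) + 1L)
  Xs <- list(); ys <- list()
  for (gi in seq_along(labelLayers)) {
    t <- labelLayers[[gi]]
    samp <- sampleBalancedDyads(getLayer(net, t), trainIdx, cfg@nPos,
                                seeds[[gi]])
    X <- forecastBlock(net, cfg, t, samp$dyadIdx, cache, order)
    if (partial) {
      masked <- maskToObserved(getLayer(net, t), trainIdx)
      ud <- sort(unique(samp$dyadIdx))
      obs <- layerFeatureBlock(masked, allDyads(net@n)[ud, , drop = FALSE],
                               r = .rankOf(cfg), lpEps = cfg@lpEps,
                               cols = selectedColumns(cfg))
      obs <- obs[match(samp$dyadIdx, ud), , drop = FALSE]
      colnames(obs) <- paste0(selectedColumns(cfg), "_obs")
      X <- cbind(X, obs)
    }
    Xs[[gi]] <- X; ys[[gi]] <- samp$y
  }
  design <- methods::new("LabeledDesign",
    X = do.call(rbind, Xs), y = unlist(ys),
    dyads = matrix(0L, length(unlist(ys)), 2L),
    groupId = rep.int(seq_along(labelLayers),
                      vapply(ys, length, integer(1))),
    setting = cfg@setting)
  fit <- trainStacker(design, cfg, seed = seeds[[length(seeds)]])
  T <- nLayers(net)
  idx <- dyadIndex(dyads[, 1L], dyads[, 2L], net@n)
  Xt <- forecastBlock(net, cfg, T, idx, cache, order)
  if (partial) {
    masked <- maskToObserved(getLayer(net, T), trainIdx)
    ud <- sort(unique(idx))
    obs <- layerFeatureBlock(masked, allDyads(net@n)[ud, , drop = FALSE],
                             r = .rankOf(cfg), lpEps = cfg@lpEps,
                             cols = selectedColumns(cfg))
    obs <- obs[match(idx, ud), , drop = FALSE]
    colnames(obs) <- paste0(selectedColumns(cfg), "_obs")
    Xt <- cbind(Xt, obs)
  }
  predictStacker(fit, Xt)
}

#' Time-series predictor as a scorer / ensemble provider
#'
#' Wraps [timeseriesPredictor()] into the provider signature. The returned
#' function re-derives the fold structure it is given through the
#' `observed` argument (the training-dyad set) when available, and
#' otherwise scores using all dyads as training folds.
#'
#' @param foldAssignment,testFold The fold structure the provider should
#'   respect.
#' @param order ARIMA order.
#' @return A function `f(net, cfg, dyads, labelLayer, observed)`.
#' @export
makeTimeseriesProvider <- function(foldAssignment, testFold,
                                   order = c(1L, 0L, 0L)) {
  cache <- new.env(parent = emptyenv())
  function(net, cfg, dyads, labelLayer, observed = NULL) {
    timeseriesPredictor(net, cfg, foldAssignment, testFold, dyads,
                        order = order, cache = cache)
  }
}
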