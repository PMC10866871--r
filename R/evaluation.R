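# Metrics, importance aggregation and the synthetic benchmark runner.

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive is scored above a
#' uniformly random negative, with tied pairs counting one half. Computed
#' from midranks, which is exactly the pairwise definition.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("both classes must be present")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Precision-recall curve and average precision
#'
#' The step-wise curve swept over score thresholds (equal scores grouped
#' into one step), and the average precision
#' \eqn{\mathrm{AP} = \sum_i (R_i - R_{i-1}) P_i}. With constant scores the
#' curve collapses to one step and AP equals the class prevalence.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return List with `curve` (data frame `threshold, precision, recall`)
#'   and `ap`.
#' @export
precisionRecall <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L || sum(labels == 0L) == 0L)
    stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  posByThr <- vapply(seq_along(thr), function(k) sum(labels[grp == k] == 1L),
                     numeric(1))
  nByThr <- vapply(seq_along(thr), function(k) sum(grp == k), numeric(1))
  tp <- cumsum(posByThr)
  npred <- cumsum(nByThr)
  precision <- tp / npred
  recall <- tp / P
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = thr, precision = precision,
                          recall = recall),
       ap = ap)
}

#' Aggregate Gini importances to base features
#'
#' Sums the per-column impurity importances of a fitted stacker over the
#' layer-offset copies of each base feature, giving one value per base
#' feature; also returns the raw per-column table and the top five base
#' features.
#'
#' @param x A fit from [trainStacker()], a [SeqstackResult-class], or a
#'   named importance vector.
#' @return List with `byFeature` (data frame, descending), `byColumn`, and
#'   `top5` (character).
#' @export
aggregateImportances <- function(x) {
  if (methods::is(x, "SeqstackResult")) {
    byColumn <- x@importance
  } else {
    imp <- if (is.list(x) && !is.null(x$importance)) x$importance else x
    if (is.null(names(imp))) stop("importances must be named")
    byColumn <- data.frame(
      column = names(imp),
      base = featureBase(sub("@t-[0-9]+$", "", names(imp))),
      offset = ifelse(grepl("@t-", names(imp)),
                      sub("^.*@", "", names(imp)), NA_character_),
      importance = as.numeric(imp), row.names = NULL)
  }
  agg <- stats::aggregate(importance ~ base, byColumn, sum)
  agg <- agg[order(-agg$importance), , drop = FALSE]
  rownames(agg) <- NULL
  list(byFeature = agg, byColumn = byColumn,
       top5 = utils::head(agg$base, 5L))
}

#' Run the synthetic benchmark
#'
#' For each simulator parameter set, seed, and prediction setting:
#' generates a realization, runs Top-Sequential-Stacking, evaluates the
#' temporal common neighbors baseline and the ground-truth oracle on the
#' same test sets, and records the exact expected oracle AUC. Failures at
#' a grid point are recorded and the run continues.
#'
#' @param paramsList List of [TSBMParams-class] (e.g. from
#'   [parameterGrid()] or a subset).
#' @param settings Character vector of prediction settings to run.
#' @param seeds Integer vector; each seed generates an independent
#'   realization (and seeds the pipeline).
#' @param nPos,repeats,numTrees,u,q,nFolds Protocol overrides (defaults are
#'   a desk scale: 1000 positives, 2 repeats).
#' @param includeTimeseries If `TRUE`, also evaluates the time-series
#'   forecasting predictor (slower).
#' @return Tidy data frame: `variant, p, mu, k, n, setting, seed, method,
#'   mean_auc, sd_auc, oracle_expected`.
#' @export
runSyntheticBenchmark <- function(paramsList,
                                  settings = c("completely_unobserved",
                                               "partially_observed"),
                                  seeds = 1:5, nPos = 1000L, repeats = 2L,
                                  numTrees = 250L, u = 6L, q = 3L,
                                  nFolds = 5L, includeTimeseries = FALSE) {
  if (methods::is(paramsList, "TSBMParams")) paramsList <- list(paramsList)
  rows <- list()
  for (params in paramsList) for (seed in seeds) {
    real <- tryCatch(generateTSBM(params, seed), error = function(e) e)
    if (inherits(real, "error")) {
      warning(sprintf("generation failed (k=%d p=%.2f mu=%.2f seed=%d): %s",
                      params@k, params@p, params@mu, seed,
                      conditionMessage(real)))
      next
    }
    orc <- oracleScores(real)
    expAUC <- expectedOracleAUC(orc)
    for (setting in settings) {
      cfg <- stackingConfig(u = u, q = q, setting = setting,
                            nFolds = nFolds, nPos = nPos,
                            repeats = repeats, seed = seed,
                            numTrees = numTrees)
      res <- tryCatch(
        runSequentialStacking(real@net, cfg,
          scorers = list(tcn = tcnProvider(),
                         oracle = makeOracleProvider(real))),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("stacking failed (k=%d p=%.2f mu=%.2f seed=%d %s): %s",
                        params@k, params@p, params@mu, seed, setting,
                        conditionMessage(res)))
        next
      }
      mk <- function(method, aucs) data.frame(
        variant = params@variant, p = params@p, mu = params@mu,
        k = params@k, n = params@n, setting = setting, seed = seed,
        method = method, mean_auc = mean(aucs),
        sd_auc = if (length(aucs) > 1L) stats::sd(aucs) else NA_real_,
        oracle_expected = expAUC)
      out <- list(mk("top_stacking", res@aucPerRun))
      for (nm in unique(res@scorerAUC$scorer))
        out[[length(out) + 1L]] <-
          mk(nm, res@scorerAUC$auc[res@scorerAUC$scorer == nm])
      if (includeTimeseries) {
        tsAUC <- tryCatch({
          s2 <- deriveSeeds(seed + 1L, 2L)
          fold <- partitionDyads(getLayer(real@net, nLayers(real@net)),
                                 nFolds, s2[[1L]])
          testIdx <- which(fold == 1L)
          samp <- sampleBalancedDyads(getLayer(real@net, nLayers(real@net)),
                                      testIdx, nPos, s2[[2L]])
          dy <- allDyads(params@n)[samp$dyadIdx, , drop = FALSE]
          sc <- timeseriesPredictor(real@net, cfg, fold, 1L, dy, seed = seed)
          aucScore(sc, samp$y)
        }, error = function(e) NA_real_)
        if (!is.na(tsAUC)) out[[length(out) + 1L]] <- mk("timeseries", tsAUC)
      }
      rows <- c(rows, out)
    }
  }
  do.call(rbind, rows)
}
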