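# Sequential stacking: designs across temporal layers, classifier, pipeline.

#' Create a stacking configuration
#'
#' Defaults follow the protocol used throughout the package's experiments:
#' `u = 6`, `q = 3` (hence `u - q = 3` training groups in the completely
#' unobserved setting, one more in the partially observed one), 5 dyad
#' folds, 10 randomized repeats (so 50 evaluation runs), and 10,000
#' positives (and as many negatives) sampled with replacement per group.
#'
#' @param u,q Search and flow variables (`u > q >= 1`).
#' @param setting `"completely_unobserved"` (features only from layers
#'   before the target) or `"partially_observed"` (training-fold edges of
#'   the target layer are additionally observable).
#' @param nFolds,repeats Cross-validation folds and randomized repeats.
#' @param nPos Positive (= negative) samples per design group.
#' @param seed Master seed; every random draw in the pipeline derives from
#'   it through counter-based sub-streams, so equal seeds give bit-identical
#'   designs and identical per-run AUCs.
#' @param numTrees,minNodeSize,mtry Random forest hyperparameters (`mtry =
#'   NULL` uses `floor(sqrt(p))`).
#' @param tune If `TRUE`, a small grid (250/500 trees, min node size 1/5) is
#'   selected by F-measure on a held-out fifth of the training design.
#' @param rank Low-rank truncation rank (`NULL` = `min(16, n - 1)`).
#' @param lpEps Local path index damping.
#' @param features Optional subset of base feature names (see
#'   [featureNames()]) to restrict every layer block to, e.g. `"CN"` for a
#'   common-neighbors-only stacker.
#' @return A [StackingConfig-class].
#' @export
stackingConfig <- function(u = 6L, q = 3L,
                           setting = c("completely_unobserved",
                                       "partially_observed"),
                           nFolds = 5L, nPos = 10000L, repeats = 10L,
                           seed = 1L, numTrees = 500L, minNodeSize = 1L,
                           mtry = NULL, tune = FALSE, rank = NULL,
                           lpEps = 0.01, features = character(0)) {
  setting <- match.arg(setting)
  methods::new("StackingConfig",
    u = as.integer(u), q = as.integer(q), setting = setting,
    nFolds = as.integer(nFolds), nPos = as.integer(nPos),
    repeats = as.integer(repeats), seed = as.integer(seed),
    numTrees = as.integer(numTrees), minNodeSize = as.integer(minNodeSize),
    mtry = as.integer(if (is.null(mtry)) 0L else mtry),
    tune = isTRUE(tune),
    rank = as.integer(if (is.null(rank)) 0L else rank),
    lpEps = as.numeric(lpEps), features = as.character(features))
}

setMethod("show", "StackingConfig", function(object) {
  cat(sprintf("StackingConfig: u=%d q=%d, %s, %d folds x %d repeats, nPos=%d, seed=%d\n",
              object@u, object@q, object@setting, object@nFolds,
              object@repeats, object@nPos, object@seed))
})

setMethod("show", "LabeledDesign", function(object) {
  cat(sprintf("LabeledDesign (%s): %d rows x %d features, %d group(s)\n",
              object@setting, nrow(object@X), ncol(object@X),
              length(unique(object@groupId))))
})

#' Partition all dyads into stratified folds
#'
#' Every unordered dyad of the node universe receives a fold id. The split
#' is stratified on edge status in the given target layer: edge counts (and
#' non-edge counts) differ by at most one between folds.
#'
#' @param target `igraph` of the target layer.
#' @param nFolds Number of folds (>= 2).
#' @param seed Seed for the random assignment.
#' @return Integer vector of fold ids over the canonical dyad order of
#'   [allDyads()].
#' @export
partitionDyads <- function(target, nFolds, seed) {
  n <- igraph::vcount(target)
  nFolds <- as.integer(nFolds)
  stopifnot(nFolds >= 2L)
  D <- choose(n, 2)
  isEdge <- logical(D)
  isEdge[edgeDyadIndices(target, n)] <- TRUE
  if (sum(isEdge) < nFolds)
    warning("fewer edges than folds; some folds will contain no edges")
  fold <- integer(D)
  withSeed(seed, {
    for (stratum in list(which(isEdge), which(!isEdge))) {
      if (!length(stratum)) next
      perm <- stratum[sample.int(length(stratum))]
      fold[perm] <- rep_len(seq_len(nFolds), length(perm))
    }
  })
  fold
}

#' Sample a balanced dyad set with replacement
#'
#' Draws `nPos` edges and `nPos` non-edges uniformly at random with
#' replacement from the allowed dyads of a label layer. Duplicates are
#' preserved, so the returned classes are always exactly balanced.
#'
#' @param layer `igraph` of the label layer.
#' @param allowed Integer vector of canonical dyad indices to draw from.
#' @param nPos Number of positives (and of negatives).
#' @param seed Seed for the draw.
#' @return List with `dyadIdx` (length `2 * nPos`, positives first) and
#'   `y` (1/0 labels).
#' @export
sampleBalancedDyads <- function(layer, allowed, nPos, seed) {
  n <- igraph::vcount(layer)
  isEdge <- logical(choose(n, 2))
  isEdge[edgeDyadIndices(layer, n)] <- TRUE
  posPool <- allowed[isEdge[allowed]]
  negPool <- allowed[!isEdge[allowed]]
  if (!length(posPool)) stop("no edges among the allowed dyads")
  if (!length(negPool)) stop("no non-edges among the allowed dyads")
  withSeed(seed, {
    pos <- posPool[sample.int(length(posPool), nPos, replace = TRUE)]
    neg <- negPool[sample.int(length(negPool), nPos, replace = TRUE)]
  })
  list(dyadIdx = c(pos, neg), y = rep(c(1L, 0L), each = as.integer(nPos)))
}

#' Restrict a layer to its observed part
#'
#' Returns the graph containing exactly those edges of `layer` whose dyad is
#' in the observed (training-fold) set. This is the partially observed view
#' of a layer: test-fold edges are invisible.
#'
#' @param layer `igraph`.
#' @param observed Integer vector of canonical dyad indices that are
#'   observable.
#' @return `igraph` on the same vertices.
#' @export
maskToObserved <- function(layer, observed) {
  n <- igraph::vcount(layer)
  idx <- edgeDyadIndices(layer, n)
  keep <- logical(choose(n, 2))
  keep[observed] <- TRUE
  graphFromDyadIndices(idx[keep[idx]], n)
}

# --- internal feature plumbing ---------------------------------------------

# Columns kept after optional base-feature subsetting.
selectedColumns <- function(cfg) {
  cols <- featureNames()
  if (length(cfg@features)) cols <- cols[featureBase(cols) %in% cfg@features]
  cols
}

.rankOf <- function(cfg) if (cfg@rank > 0L) cfg@rank else NULL

# Full-dyad feature block of an unmasked layer, cached per layer index.
cachedLayerBlock <- function(net, t, cfg, cache) {
  key <- as.character(t)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  blk <- layerFeatureBlock(getLayer(net, t), dyads = NULL,
                           r = .rankOf(cfg), lpEps = cfg@lpEps,
                           cols = selectedColumns(cfg))
  if (!is.null(cache)) cache[[key]] <- blk
  blk
}

# Stacked feature rows for sampled dyads of one group: q trailing unmasked
# layers, optionally one masked layer block appended (offset "t-0").
stackedRows <- function(net, cfg, labelLayer, dyadIdx, cache,
                        maskedGraph = NULL) {
  q <- cfg@q
  cols <- selectedColumns(cfg)
  blocks <- vector("list", q + !is.null(maskedGraph))
  for (s in seq_len(q)) {
    t <- labelLayer - q + s - 1L       # offsets t-q .. t-1
    blk <- cachedLayerBlock(net, t, cfg, cache)[dyadIdx, , drop = FALSE]
    colnames(blk) <- paste0(cols, "@t-", q - s + 1L)
    blocks[[s]] <- blk
  }
  if (!is.null(maskedGraph)) {
    ud <- sort(unique(dyadIdx))
    blk <- layerFeatureBlock(maskedGraph,
                             dyads = allDyads(net@n)[ud, , drop = FALSE],
                             r = .rankOf(cfg), lpEps = cfg@lpEps,
                             cols = cols)
    blk <- blk[match(dyadIdx, ud), , drop = FALSE]
    colnames(blk) <- paste0(cols, "@t-0")
    blocks[[q + 1L]] <- blk
  }
  do.call(cbind, blocks)
}

# Append one column per ensemble provider to a group's feature rows.
providerColumns <- function(providers, net, cfg, dyads, labelLayer, observed) {
  if (!length(providers)) return(NULL)
  nm <- names(providers)
  if (is.null(nm) || any(nm == ""))
    stop("ensemble providers must be a named list")
  cols <- lapply(nm, function(name) {
    s <- providers[[name]](net, cfg, dyads, labelLayer, observed)
    if (length(s) != nrow(dyads) || !all(is.finite(s)))
      stop(sprintf("ensemble provider '%s' returned %s",
                   name,
                   if (length(s) != nrow(dyads)) "the wrong number of scores"
                   else "non-finite scores"))
    s
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("ens_", nm)
  out
}

trainingLabelLayers <- function(net, cfg) {
  T <- nLayers(net)
  if (T < cfg@u + 1L)
    stop(sprintf("need at least u + 1 = %d layers, have %d", cfg@u + 1L, T))
  (T - cfg@u + cfg@q):(T - 1L)
}

#' Build the stacked training design
#'
#' One training group per label layer `t` in the `u - q` layers preceding
#' the target: features stacked from layers `t-q .. t-1`, labels sampled
#' (balanced, with replacement) from layer `t` restricted to training-fold
#' dyads. In the partially observed setting each group gains a 41-column
#' block computed on the observed part of its label layer (training-fold
#' edges only), and one extra group uses the target layer itself as label
#' layer, giving `u - q + 1` groups.
#'
#' @param net A [TemporalNetwork-class].
#' @param cfg A [StackingConfig-class].
#' @param foldAssignment Integer fold id per canonical dyad (from
#'   [partitionDyads()]).
#' @param testFold Fold id held out for testing.
#' @param seed Seed for the per-group sampling (defaults to `cfg@seed`).
#' @param ensembleProviders Named list of external scorers appended as extra
#'   feature columns (see [runSequentialStacking()]).
#' @param cache Optional environment reusing full-dyad layer blocks.
#' @return A [LabeledDesign-class] with `2 * nPos` rows per group.
#' @export
buildTrainingDesign <- function(net, cfg, foldAssignment, testFold,
                                seed = cfg@seed,
                                ensembleProviders = list(), cache = NULL) {
  trainIdx <- which(foldAssignment != testFold)
  labelLayers <- trainingLabelLayers(net, cfg)
  partial <- cfg@setting == "partially_observed"
  if (partial) labelLayers <- c(labelLayers, nLayers(net))
  seeds <- deriveSeeds(seed, length(labelLayers))
  parts <- vector("list", length(labelLayers))
  for (gi in seq_along(labelLayers)) {
    t <- labelLayers[[gi]]
    samp <- sampleBalancedDyads(getLayer(net, t), trainIdx, cfg@nPos,
                                seeds[[gi]])
    masked <- if (partial) maskToObserved(getLayer(net, t), trainIdx)
    X <- stackedRows(net, cfg, t, samp$dyadIdx, cache, masked)
    dy <- allDyads(net@n)[samp$dyadIdx, , drop = FALSE]
    ens <- providerColumns(ensembleProviders, net, cfg, dy, t,
                           if (partial) trainIdx)
    if (!is.null(ens)) X <- cbind(X, ens)
    parts[[gi]] <- list(X = X, y = samp$y, dyads = dy,
                        g = rep.int(gi, length(samp$y)))
  }
  methods::new("LabeledDesign",
    X = do.call(rbind, lapply(parts, `[[`, "X")),
    y = unlist(lapply(parts, `[[`, "y")),
    dyads = do.call(rbind, lapply(parts, `[[`, "dyads")),
    groupId = unlist(lapply(parts, `[[`, "g")),
    setting = cfg@setting)
}

#' Build the stacked test design
#'
#' Labels are sampled (balanced, with replacement) from the test-fold dyads
#' of the target layer; features come from the `q` layers preceding the
#' target and — in the partially observed setting — from the observed part
#' of the target layer, built from training-fold dyads only. No test-fold
#' edge of the target layer ever contributes to a feature value.
#'
#' @inheritParams buildTrainingDesign
#' @param dyadIdx Optional pre-sampled canonical dyad indices (with labels
#'   taken from the target layer); mainly for leakage checks. Default
#'   `NULL` samples `2 * nPos` balanced rows.
#' @return A [LabeledDesign-class].
#' @export
buildTestDesign <- function(net, cfg, foldAssignment, testFold,
                            seed = cfg@seed, ensembleProviders = list(),
                            cache = NULL, dyadIdx = NULL) {
  T <- nLayers(net)
  trainingLabelLayers(net, cfg)  # validates u against the layer count
  target <- getLayer(net, T)
  testIdx <- which(foldAssignment == testFold)
  trainIdx <- which(foldAssignment != testFold)
  if (is.null(dyadIdx)) {
    samp <- sampleBalancedDyads(target, testIdx, cfg@nPos, seed)
  } else {
    isEdge <- logical(choose(net@n, 2))
    isEdge[edgeDyadIndices(target, net@n)] <- TRUE
    samp <- list(dyadIdx = dyadIdx, y = as.integer(isEdge[dyadIdx]))
  }
  partial <- cfg@setting == "partially_observed"
  masked <- if (partial) maskToObserved(target, trainIdx)
  X <- stackedRows(net, cfg, T, samp$dyadIdx, cache, masked)
  dy <- allDyads(net@n)[samp$dyadIdx, , drop = FALSE]
  ens <- providerColumns(ensembleProviders, net, cfg, dy, T,
                         if (partial) trainIdx)
  if (!is.null(ens)) X <- cbind(X, ens)
  methods::new("LabeledDesign", X = X, y = samp$y, dyads = dy,
               groupId = rep.int(0L, length(samp$y)), setting = cfg@setting)
}

# --- classifier -------------------------------------------------------------

fMeasure <- function(truth, pred) {
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

fitForest <- function(X, y, cfg, seed, numTrees = cfg@numTrees,
                      minNodeSize = cfg@minNodeSize) {
  ranger::ranger(
    x = as.data.frame(X), y = factor(y, levels = c(0L, 1L)),
    probability = TRUE, num.trees = numTrees,
    mtry = if (cfg@mtry > 0L) cfg@mtry else floor(sqrt(ncol(X))),
    min.node.size = minNodeSize, importance = "impurity",
    seed = seed, num.threads = 1L)
}

#' Train the stacking classifier
#'
#' Fits a random forest (bootstrap-aggregated decision trees) on a labeled
#' design and exposes normalized Gini (impurity-decrease) importances. With
#' `cfg@tune = TRUE` a small hyperparameter grid is first selected by
#' F-measure on a held-out fifth of the rows.
#'
#' @param design A [LabeledDesign-class] containing both classes.
#' @param cfg A [StackingConfig-class].
#' @param seed Seed for the forest (defaults to `cfg@seed`).
#' @return List with elements `model` (the `ranger` fit) and `importance`
#'   (named numeric, summing to 1).
#' @export
trainStacker <- function(design, cfg, seed = cfg@seed) {
  y <- design@y
  if (length(unique(y)) < 2L)
    stop("training design contains a single class")
  X <- design@X
  numTrees <- cfg@numTrees
  minNode <- cfg@minNodeSize
  if (cfg@tune) {
    seeds <- deriveSeeds(seed, 2L)
    hold <- withSeed(seeds[[1L]],
                     sample.int(nrow(X), max(2L, floor(nrow(X) / 5))))
    grid <- expand.grid(trees = c(250L, 500L), minNode = c(1L, 5L))
    f1 <- apply(grid, 1L, function(gpar) {
      fit <- fitForest(X[-hold, , drop = FALSE], y[-hold], cfg, seeds[[2L]],
                       numTrees = gpar[["trees"]],
                       minNodeSize = gpar[["minNode"]])
      p <- stats::predict(fit, data = as.data.frame(X[hold, , drop = FALSE]))
      fMeasure(y[hold], as.integer(p$predictions[, "1"] > 0.5))
    })
    best <- grid[which.max(f1), ]
    numTrees <- best$trees
    minNode <- best$minNode
  }
  model <- fitForest(X, y, cfg, seed, numTrees = numTrees,
                     minNodeSize = minNode)
  imp <- model$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(model = model, importance = imp)
}

#' Score dyads with a trained stacker
#'
#' @param fit Result of [trainStacker()].
#' @param X Feature matrix with the same columns the stacker was trained on.
#' @return Numeric vector of edge probabilities.
#' @export
predictStacker <- function(fit, X) {
  stats::predict(fit$model, data = as.data.frame(X))$predictions[, "1"]
}

# --- full pipeline ----------------------------------------------------------

#' Run the sequential stacking link prediction pipeline
#'
#' The full protocol: for each of `repeats` randomized repeats, the dyads of
#' the node universe are partitioned into `nFolds` stratified folds; each
#' fold in turn is held out, a stacked training design is built from the
#' layers before the target (see [buildTrainingDesign()]), a random forest
#' is trained, and the held-out fold's balanced test sample of the target
#' layer is scored. With the defaults (10 repeats, 5 folds) this yields 50
#' evaluation runs whose AUCs are averaged.
#'
#' With topological features only this is Top-Sequential-Stacking; supplying
#' `ensembleProviders` appends one score column per provider to every
#' design (Ensemble-Sequential-Stacking). A provider is a function
#' `f(net, cfg, dyads, labelLayer, observed)` returning one finite score per
#' row of `dyads`; it is called for training groups (with their label
#' layer) as well as for the test set, and must only use information
#' available before its label layer (plus the observed part, when given).
#'
#' @param net A [TemporalNetwork-class] with at least `u + 1` layers.
#' @param cfg A [StackingConfig-class].
#' @param ensembleProviders Named list of provider functions (may be empty).
#' @param scorers Named list of additional scorers with the provider
#'   signature, evaluated on each run's test set for comparison (they do
#'   not enter the stacker).
#' @return A [SeqstackResult-class].
#' @seealso [temporalCommonNeighbors()], [makeOracleProvider()],
#'   [makeTimeseriesProvider()]
#' @export
runSequentialStacking <- function(net, cfg, ensembleProviders = list(),
                                  scorers = list()) {
  T <- nLayers(net)
  target <- getLayer(net, T)
  cache <- new.env(parent = emptyenv())
  repSeeds <- deriveSeeds(cfg@seed, cfg@repeats)
  aucs <- numeric(0); aps <- numeric(0)
  impSum <- NULL
  scoreRows <- list()
  scorerRows <- list()
  for (r in seq_len(cfg@repeats)) {
    s <- deriveSeeds(repSeeds[[r]], 1L + 3L * cfg@nFolds)
    foldAssign <- partitionDyads(target, cfg@nFolds, s[[1L]])
    for (f in seq_len(cfg@nFolds)) {
      sTrain <- s[[1L + 3L * (f - 1L) + 1L]]
      sTest  <- s[[1L + 3L * (f - 1L) + 2L]]
      sForest <- s[[1L + 3L * (f - 1L) + 3L]]
      train <- buildTrainingDesign(net, cfg, foldAssign, f, seed = sTrain,
                                   ensembleProviders = ensembleProviders,
                                   cache = cache)
      test <- buildTestDesign(net, cfg, foldAssign, f, seed = sTest,
                              ensembleProviders = ensembleProviders,
                              cache = cache)
      fit <- trainStacker(train, cfg, seed = sForest)
      sc <- predictStacker(fit, test@X)
      aucs <- c(aucs, aucScore(sc, test@y))
      aps <- c(aps, precisionRecall(sc, test@y)$ap)
      impSum <- if (is.null(impSum)) fit$importance else impSum + fit$importance
      scoreRows[[length(scoreRows) + 1L]] <- data.frame(
        i = test@dyads[, 1L], j = test@dyads[, 2L], score = sc,
        label = test@y, fold = f, rep = r)
      if (length(scorers)) {
        trainIdx <- which(foldAssign != f)
        observed <- if (cfg@setting == "partially_observed") trainIdx
        for (nm in names(scorers)) {
          ssc <- scorers[[nm]](net, cfg, test@dyads, T, observed)
          scorerRows[[length(scorerRows) + 1L]] <- data.frame(
            scorer = nm, fold = f, rep = r, auc = aucScore(ssc, test@y))
        }
      }
    }
  }
  nRuns <- length(aucs)
  impMean <- impSum / nRuns
  importance <- data.frame(
    column = names(impMean),
    base = featureBase(sub("@t-[0-9]+$", "", names(impMean))),
    offset = ifelse(grepl("@t-", names(impMean)),
                    sub("^.*@", "", names(impMean)), NA_character_),
    importance = as.numeric(impMean),
    row.names = NULL)
  methods::new("SeqstackResult",
    aucPerRun = aucs, apPerRun = aps, importance = importance,
    scores = do.call(rbind, scoreRows),
    scorerAUC = if (length(scorerRows)) do.call(rbind, scorerRows)
                else data.frame(scorer = character(0), fold = integer(0),
                                rep = integer(0), auc = numeric(0)),
    config = cfg)
}

#' @rdname meanAUC
#' @export
setMethod("meanAUC", "SeqstackResult", function(x) mean(x@aucPerRun))

#' @rdname meanAP
#' @export
setMethod("meanAP", "SeqstackResult", function(x) mean(x@apPerRun))

setMethod("show", "SeqstackResult", function(object) {
  cat(sprintf("SeqstackResult (%s): mean AUC %.4f over %d runs, mean AP %.4f\n",
              object@config@setting, mean(object@aucPerRun),
              length(object@aucPerRun), mean(object@apPerRun)))
  if (nrow(object@scorerAUC)) {
    agg <- stats::aggregate(auc ~ scorer, object@scorerAUC, mean)
    for (k in seq_len(nrow(agg)))
      cat(sprintf("  scorer %s: mean AUC %.4f\n", agg$scorer[k], agg$auc[k]))
  }
})
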