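# S4 classes for the sequential stacking framework.

#' TemporalNetwork: an ordered sequence of simple graphs on a fixed node set
#'
#' A temporal network is a list of `T` simple undirected graphs (layers) that
#' all share the same node universe `1..n`. Nodes never appear or disappear:
#' a node without incident edges in some layer is simply isolated there.
#' Layers are indexed `1..T` in R; the on-disk edge-list dialect is 0-based
#' (see [readTemporalEdgelist()]).
#'
#' @slot n Integer node count.
#' @slot layers List of `igraph` objects, each undirected and simple with
#'   exactly `n` vertices.
#' @seealso [temporalNetwork()], [readTemporalEdgelist()], [getLayer()]
#' @export
setClass("TemporalNetwork",
  representation(n = "integer", layers = "list"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
      msgs <- c(msgs, "n must be a single positive integer")
    if (length(object@layers) < 1L)
      msgs <- c(msgs, "at least one layer is required")
    for (t in seq_along(object@layers)) {
      g <- object@layers[[t]]
      if (!igraph::is_igraph(g)) {
        msgs <- c(msgs, sprintf("layer %d is not an igraph object", t))
        next
      }
      if (igraph::is_directed(g))
        msgs <- c(msgs, sprintf("layer %d is directed", t))
      if (igraph::vcount(g) != object@n)
        msgs <- c(msgs, sprintf("layer %d has %d vertices, expected %d",
                                t, igraph::vcount(g), object@n))
      if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g)))
        msgs <- c(msgs, sprintf("layer %d is not simple", t))
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' StackingConfig: parameters of a sequential stacking run
#'
#' Bundles the search variable `u` (how many layers before the target are
#' available for building training groups), the flow variable `q` (how many
#' consecutive layers are concatenated into one stacked feature vector), the
#' prediction setting, sampling sizes, and classifier options.
#'
#' @slot u Integer search variable; `u > q`.
#' @slot q Integer flow variable; `q >= 1`.
#' @slot setting `"completely_unobserved"` or `"partially_observed"`.
#' @slot nFolds Integer number of dyad cross-validation folds (>= 2).
#' @slot nPos Integer positives (and negatives) sampled per design group.
#' @slot repeats Integer randomized repeats of the cross-validation.
#' @slot seed Integer master seed; all randomness derives from it.
#' @slot numTrees,minNodeSize,mtry Random forest hyperparameters
#'   (`mtry = 0` means the default `floor(sqrt(p))`).
#' @slot tune Logical; if `TRUE` a small hyperparameter grid is selected by
#'   F-measure on a held-out slice before the final fit.
#' @slot rank Integer rank of the low-rank adjacency approximation
#'   (`0` means `min(16, n - 1)`).
#' @slot lpEps Numeric damping of the cubic term in the local path index.
#' @slot features Character vector of base feature names to restrict the
#'   bank to (empty = all 41); see [featureNames()].
#' @seealso [stackingConfig()], [runSequentialStacking()]
#' @export
setClass("StackingConfig",
  representation(u = "integer", q = "integer", setting = "character",
                 nFolds = "integer", nPos = "integer", repeats = "integer",
                 seed = "integer", numTrees = "integer",
                 minNodeSize = "integer", mtry = "integer", tune = "logical",
                 rank = "integer", lpEps = "numeric", features = "character"),
  validity = function(object) {
    msgs <- character(0)
    if (!(object@q >= 1L)) msgs <- c(msgs, "q must be >= 1")
    if (!(object@u > object@q)) msgs <- c(msgs, "u must exceed q")
    if (!object@setting %in% c("completely_unobserved", "partially_observed"))
      msgs <- c(msgs, "setting must be 'completely_unobserved' or 'partially_observed'")
    if (!(object@nFolds >= 2L)) msgs <- c(msgs, "nFolds must be >= 2")
    if (!(object@nPos >= 1L)) msgs <- c(msgs, "nPos must be >= 1")
    if (!(object@repeats >= 1L)) msgs <- c(msgs, "repeats must be >= 1")
    if (!(object@numTrees >= 1L)) msgs <- c(msgs, "numTrees must be >= 1")
    if (object@lpEps < 0) msgs <- c(msgs, "lpEps must be >= 0")
    bad <- setdiff(object@features, featureNames(base = TRUE))
    if (length(bad))
      msgs <- c(msgs, paste0("unknown feature name(s): ",
                             paste(bad, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
  }
)

#' LabeledDesign: a stacked feature matrix with edge labels
#'
#' Rows are sampled dyads; columns are per-layer feature blocks concatenated
#' across the `q` layers preceding each group's label layer (plus the
#' partially observed target block and any ensemble provider columns).
#'
#' @slot X Numeric feature matrix.
#' @slot y Integer labels (1 = edge in the label layer, 0 = non-edge).
#' @slot dyads Integer matrix (i, j) aligned to the rows of `X`.
#' @slot groupId Integer training-group id per row (1 = furthest back).
#' @slot setting Prediction setting the design was built for.
#' @export
setClass("LabeledDesign",
  representation(X = "matrix", y = "integer", dyads = "matrix",
                 groupId = "integer", setting = "character"),
  validity = function(object) {
    msgs <- character(0)
    nr <- nrow(object@X)
    if (length(object@y) != nr) msgs <- c(msgs, "length(y) != nrow(X)")
    if (nrow(object@dyads) != nr) msgs <- c(msgs, "nrow(dyads) != nrow(X)")
    if (length(object@groupId) != nr) msgs <- c(msgs, "length(groupId) != nrow(X)")
    if (!all(object@y %in% c(0L, 1L))) msgs <- c(msgs, "labels must be 0/1")
    if (length(msgs)) msgs else TRUE
  }
)

#' TSBMParams: parameters of a degree-corrected temporal SBM
#'
#' Both simulator variants draw each layer's edges independently given a
#' latent state, from the degree-corrected planted partition probability
#' \deqn{P_{ij} = \min\{1,\ \theta_i \theta_j (c/n)[(1-\mu) k \delta_{g_i g_j} + \mu]\}.}
#' In the community-label variant the latent node labels are re-drawn each
#' layer (copied with probability `p`); in the edge-correlated variant the
#' labels are fixed and each dyad's edge indicator is copied with
#' probability `p`, otherwise re-sampled from its block probability.
#'
#' @slot n,layers,k Integers: nodes, layer count, communities.
#' @slot p Temporal dependency: label copy probability (community-label) or
#'   edge copy probability (edge-correlated).
#' @slot mu Fraction of edges placed uniformly at random on top of the block
#'   structure.
#' @slot c Target mean degree.
#' @slot theta Per-node degree propensities with mean 1. May be empty, in
#'   which case [generateTSBM()] draws them (uniform on \[0.5, 1.5\],
#'   normalized) and stores the realization's concrete values.
#' @slot thetaHet Logical; if `FALSE`, `theta` is identically 1.
#' @slot variant `"community_label"` or `"edge_correlated"`.
#' @seealso [tsbmParams()], [generateTSBM()], [blockProbability()]
#' @export
setClass("TSBMParams",
  representation(n = "integer", layers = "integer", k = "integer",
                 p = "numeric", mu = "numeric", c = "numeric",
                 theta = "numeric", thetaHet = "logical",
                 variant = "character"),
  validity = function(object) {
    msgs <- character(0)
    if (object@p < 0 || object@p > 1) msgs <- c(msgs, "p must be in [0, 1]")
    if (object@mu < 0 || object@mu > 1) msgs <- c(msgs, "mu must be in [0, 1]")
    if (object@k < 1L || object@k > object@n)
      msgs <- c(msgs, "k must be in 1..n")
    if (object@c <= 0) msgs <- c(msgs, "c must be positive")
    if (object@layers < 1L) msgs <- c(msgs, "layers must be >= 1")
    if (!object@variant %in% c("community_label", "edge_correlated"))
      msgs <- c(msgs, "variant must be 'community_label' or 'edge_correlated'")
    if (length(object@theta)) {
      if (length(object@theta) != object@n)
        msgs <- c(msgs, "theta must have length n")
      else if (abs(mean(object@theta) - 1) > 1e-9)
        msgs <- c(msgs, "theta must have mean 1")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' TSBMRealization: one simulated temporal network plus its latent state
#'
#' @slot net The simulated [TemporalNetwork-class].
#' @slot labels Integer matrix of community labels: one row per layer for the
#'   community-label variant, a single row for the edge-correlated variant.
#' @slot params The [TSBMParams-class] used, with `theta` made concrete.
#' @seealso [generateTSBM()], [oracleScores()]
#' @export
setClass("TSBMRealization",
  representation(net = "TemporalNetwork", labels = "matrix",
                 params = "TSBMParams"))

#' OracleScores: ground-truth target-layer connection probabilities
#'
#' The oracle conditions on the realized latent state (the target layer's
#' community labels, or the previous layer's adjacency for the
#' edge-correlated model) and scores every dyad with its true connection
#' probability. No predictor can beat it in expectation.
#'
#' @slot probs Numeric vector of probabilities over the canonical dyad order
#'   of [allDyads()].
#' @slot conditioning Human-readable description of the conditioned state.
#' @slot n Node count (so `length(probs) == choose(n, 2)`).
#' @seealso [oracleScores()], [expectedOracleAUC()], [oracleAUC()]
#' @export
setClass("OracleScores",
  representation(probs = "numeric", conditioning = "character", n = "integer"),
  validity = function(object) {
    if (any(object@probs < 0 | object@probs > 1))
      return("all probabilities must lie in [0, 1]")
    if (length(object@probs) != choose(object@n, 2))
      return("length(probs) must equal choose(n, 2)")
    TRUE
  }
)

#' SeqstackResult: output of a sequential stacking run
#'
#' @slot aucPerRun Numeric AUC per (repeat, fold) run.
#' @slot apPerRun Numeric average precision per run.
#' @slot importance Data frame of mean normalized Gini importances per
#'   stacked column (with base feature and layer offset).
#' @slot scores Data frame of test-dyad scores
#'   (`i, j, score, label, fold, rep`).
#' @slot scorerAUC Data frame of per-run AUCs of any additional scorers
#'   evaluated on the same test sets (empty if none).
#' @slot config The [StackingConfig-class] used.
#' @export
setClass("SeqstackResult",
  representation(aucPerRun = "numeric", apPerRun = "numeric",
                 importance = "data.frame", scores = "data.frame",
                 scorerAUC = "data.frame", config = "StackingConfig"))
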