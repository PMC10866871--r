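#' Number of nodes in the shared node universe
#' @param x A [TemporalNetwork-class].
#' @return Integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of temporal layers
#' @param x A [TemporalNetwork-class].
#' @return Integer layer count `T` (layers are indexed `1..T`).
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Extract one layer as an igraph object
#' @param x A [TemporalNetwork-class].
#' @param t Layer index in `1..nLayers(x)`.
#' @return An undirected simple `igraph` on the full node universe.
#' @export
setGeneric("getLayer", function(x, t) standardGeneric("getLayer"))

#' Mean AUC of a sequential stacking run
#' @param x A [SeqstackResult-class].
#' @return Arithmetic mean of the per-run AUC values.
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' Mean average precision of a sequential stacking run
#' @param x A [SeqstackResult-class].
#' @return Arithmetic mean of the per-run average precision values.
#' @export
setGeneric("meanAP", function(x) standardGeneric("meanAP"))

#' Oracle probabilities as a plain vector
#' @param x An [OracleScores-class].
#' @return Numeric vector over the canonical dyad order.
#' @export
setGeneric("oracleProbs", function(x) standardGeneric("oracleProbs"))
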