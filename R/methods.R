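#' Accessors for HybridNetwork objects
#'
#' @param object a [HybridNetwork].
#' @return \code{nodeIds}: character vector of node ids. \code{nodeKinds}:
#'   character vector named by id. \code{edgeTable}: data.frame with
#'   columns \code{a}, \code{b}, \code{score}, \code{kind}. \code{numNodes},
#'   \code{numEdges}: integer counts.
#' @name HybridNetwork-accessors
NULL

#' @rdname HybridNetwork-accessors
#' @export
setMethod("nodeIds", "HybridNetwork", function(object) object@nodes$id)

#' @rdname HybridNetwork-accessors
#' @export
setMethod("nodeKinds", "HybridNetwork", function(object)
  stats::setNames(object@nodes$kind, object@nodes$id))

#' @rdname HybridNetwork-accessors
#' @export
setMethod("edgeTable", "HybridNetwork", function(object) object@edges)

#' @rdname HybridNetwork-accessors
#' @export
setMethod("numNodes", "HybridNetwork", function(object) nrow(object@nodes))

#' @rdname HybridNetwork-accessors
#' @export
setMethod("numEdges", "HybridNetwork", function(object) nrow(object@edges))

setMethod("show", "HybridNetwork", function(object) {
  kinds <- table(factor(object@edges$kind, levels = .edgeKinds))
  cat("HybridNetwork with", nrow(object@nodes), "nodes (",
      sum(object@nodes$kind == "compound"), "compounds,",
      sum(object@nodes$kind == "enzyme"), "enzymes ) and",
      nrow(object@edges), "interactions\n")
  cat("  cc:", kinds[["cc"]], " cp:", kinds[["cp"]],
      " pp:", kinds[["pp"]], "\n")
  if (nrow(object@edges))
    cat("  confidence scores in [", min(object@edges$score), ",",
        max(object@edges$score), "]\n")
})

#' Interaction partners of a node
#'
#' Returns the neighbor set \eqn{N(s)} of a node with the confidence score
#' and kind of each incident interaction. The relation is symmetric:
#' \code{b} is a neighbor of \code{a} iff \code{a} is a neighbor of
#' \code{b}, with the same score.
#'
#' @param object a [HybridNetwork].
#' @param node a node id present in the network.
#' @return data.frame with columns \code{id}, \code{score}, \code{kind},
#'   one row per interaction partner (zero rows for an isolated node).
#' @examples
#' fx <- exampleNetwork("C07277")
#' neighbors(fx$network, "C07277")
#' @name neighbors
#' @export
setMethod("neighbors", "HybridNetwork", function(object, node) {
  node <- toupper(node)
  if (!node %in% object@nodes$id)
    stop("unknown node id: ", node)
  ed <- object@edges
  hit <- ed$a == node | ed$b == node
  data.frame(
    id = ifelse(ed$a[hit] == node, ed$b[hit], ed$a[hit]),
    score = ed$score[hit],
    kind = ed$kind[hit],
    stringsAsFactors = FALSE
  )
})

#' Accessors for LabelTable objects
#'
#' @param object a [LabelTable].
#' @param node a node id.
#' @return \code{membershipMatrix}: the logical nodes-by-11 membership
#'   matrix. \code{nodeClasses}: character vector of class tags for one
#'   node. \code{labelCounts}: integer vector \eqn{N_i} (classes per node),
#'   named by id.
#' @name LabelTable-accessors
NULL

#' @rdname LabelTable-accessors
#' @export
setMethod("membershipMatrix", "LabelTable", function(object)
  object@membership)

#' @rdname LabelTable-accessors
#' @export
setMethod("nodeClasses", "LabelTable", function(object, node) {
  node <- toupper(node)
  if (!node %in% rownames(object@membership))
    stop("node has no label row: ", node)
  colnames(object@membership)[object@membership[node, ]]
})

#' @rdname LabelTable-accessors
#' @export
setMethod("labelCounts", "LabelTable", function(object)
  stats::setNames(as.integer(rowSums(object@membership)),
                  rownames(object@membership)))

#' @rdname LabelTable-accessors
#' @export
setMethod("nodeKinds", "LabelTable", function(object) object@kind)

#' @rdname LabelTable-accessors
#' @export
setMethod("nodeIds", "LabelTable", function(object) {
  ids <- rownames(object@membership)
  if (is.null(ids)) character(0) else ids
})

setMethod("show", "LabelTable", function(object) {
  n <- nrow(object@membership)
  cat("LabelTable for", n, "nodes (",
      sum(object@kind == "compound"), "compounds,",
      sum(object@kind == "enzyme"), "enzymes )\n")
  if (n) {
    ni <- rowSums(object@membership)
    cat("  class memberships:", sum(ni),
        sprintf("(mean %.2f per node, %d multi-label)\n",
                mean(ni), sum(ni > 1)))
  }
})

#' @describeIn RankedPrediction coerce to a rank/class/likelihood
#'   data.frame.
#' @param x a \code{RankedPrediction}.
#' @param ... ignored.
#' @export
as.data.frame.RankedPrediction <- function(x, ...) {
  data.frame(rank = seq_along(x@order), class = x@order,
             likelihood = x@values, stringsAsFactors = FALSE)
}

setMethod("show", "RankedPrediction", function(object) {
  cat("RankedPrediction for", object@query, "\n")
  df <- as.data.frame.RankedPrediction(object)
  print(df, row.names = FALSE)
})

#' @describeIn RankedPrediction the predicted class tags, best first.
#' @param object a \code{RankedPrediction}.
#' @export
predictedOrder <- function(object) object@order

#' @describeIn RankedPrediction the likelihoods in ranked order.
#' @export
likelihoodValues <- function(object)
  stats::setNames(object@values, object@order)

#' @describeIn RankedPrediction the query node id.
#' @export
queryId <- function(object) object@query

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", object@nSamples, "samples\n")
  cat(sprintf("  average label count M = %.4f (%d/%d), ceiling %d\n",
              object@avgLabels, object@labelTotal, object@nSamples,
              object@mUsed))
  cat(sprintf("  random-guess baseline M/11 = %.2f%%\n",
              100 * object@randomGuess))
  cat(sprintf("  coverage L_%d = %.2f%%\n", object@mUsed,
              100 * object@coverage))
  cat("  ordered accuracies ACC_1..ACC_11 (%):\n")
  cat("   ", paste(sprintf("%.2f", 100 * object@orderedAccuracy),
                   collapse = " "), "\n")
})

#' Accessors for EvaluationReport objects
#'
#' @param object an [EvaluationReport].
#' @return \code{orderedAccuracy}: the 11 fractions \eqn{ACC_j};
#'   \code{coverageL}: the coverage \eqn{L_m} with its \eqn{m} in
#'   attribute \code{"m"}; \code{perSampleResults}: one row per evaluated
#'   sample with its true classes, full ranking and first-order outcome.
#' @name EvaluationReport-accessors
NULL

#' @rdname EvaluationReport-accessors
#' @export
orderedAccuracyValues <- function(object) object@orderedAccuracy

#' @rdname EvaluationReport-accessors
#' @export
coverageL <- function(object)
  structure(object@coverage, m = object@mUsed)

#' @rdname EvaluationReport-accessors
#' @export
perSampleResults <- function(object) object@perSample
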