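#' Class likelihoods of a query node
#'
#' The likelihood that query \eqn{s} belongs to pathway class \eqn{M_j} is
#' the sum of the confidence scores of the interactions joining \eqn{s} to
#' neighbors that belong to \eqn{M_j}:
#' \deqn{F(s, M_j) = \sum_{t \in N(s)} Q(s, t)\,[M_j \in labels(t)].}
#' A neighbor with several classes contributes its score once per class.
#' The query's own labels are never consulted, which is what makes the
#' leave-one-out jackknife of [jackknife()] exact. Likelihoods are
#' unnormalized integer sums and are kept so; a zero entry means no
#' labeled neighbor carries that class.
#'
#' @param network a [HybridNetwork].
#' @param labels a [LabelTable]; neighbors absent from it contribute
#'   nothing (the loader drops such edges up front).
#' @param node the query node id.
#' @return Named integer vector of length 11 (names \code{M1..M11}).
#' @examples
#' fx <- exampleNetwork("C07277")
#' pathwayLikelihood(fx$network, fx$labels, "YLL058W")
#' @export
pathwayLikelihood <- function(network, labels, node) {
  nb <- neighbors(network, node)  # errors on unknown node
  v <- stats::setNames(integer(11), .classTags())
  if (nrow(nb) == 0) return(v)
  m <- membershipMatrix(labels)
  idx <- match(nb$id, rownames(m))
  hit <- !is.na(idx)
  if (!any(hit)) return(v)
  contrib <- m[idx[hit], , drop = FALSE] * nb$score[hit]
  stats::setNames(as.integer(colSums(contrib)), .classTags())
}

#' Likelihood matrix for many queries at once
#'
#' Computes \eqn{F(s, M_j)} for every query in one sparse matrix product:
#' with \eqn{A} the symmetric score-weighted adjacency matrix and \eqn{Y}
#' the 0/1 membership matrix, the likelihood matrix is \eqn{A Y}. Because
#' the diagonal of \eqn{A} is zero, row \eqn{s} never sees \eqn{s}'s own
#' labels, so this is simultaneously the leave-one-out computation for
#' every sample.
#'
#' @inheritParams pathwayLikelihood
#' @param nodes character vector of query ids (default: all network
#'   nodes).
#' @return Integer matrix, queries in rows, classes \code{M1..M11} in
#'   columns.
#' @export
likelihoodMatrix <- function(network, labels, nodes = nodeIds(network)) {
  nodes <- toupper(nodes)
  allIds <- nodeIds(network)
  unknown <- setdiff(nodes, allIds)
  if (length(unknown))
    stop("unknown node id: ", unknown[1])
  ed <- edgeTable(network)
  n <- length(allIds)
  m <- membershipMatrix(labels)
  Y <- matrix(0, nrow = n, ncol = 11,
              dimnames = list(allIds, .classTags()))
  common <- intersect(allIds, rownames(m))
  Y[common, ] <- m[common, ] + 0
  if (nrow(ed)) {
    i <- match(ed$a, allIds)
    j <- match(ed$b, allIds)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(ed$score, 2), dims = c(n, n))
    L <- as.matrix(A %*% Y)
  } else {
    L <- matrix(0, nrow = n, ncol = 11)
  }
  dimnames(L) <- list(allIds, .classTags())
  storage.mode(L) <- "integer"
  L[nodes, , drop = FALSE]
}

#' Rank the 11 classes by likelihood
#'
#' Produces the full ordered prediction: position \eqn{k} is the
#' \eqn{k}-th order predicted pathway class, classes sorted by descending
#' likelihood. Ties — including all classes with likelihood zero — are
#' broken by ascending class index, so every query yields the same
#' deterministic permutation of all 11 classes on every run. Zero
#' likelihoods mean "no evidence" but the class is still ranked, after
#' every positive class.
#'
#' @param values numeric vector of 11 likelihoods, in class order
#'   \code{M1..M11} (names, if present, are checked).
#' @param query node id recorded in the result.
#' @return A [RankedPrediction] over all 11 classes.
#' @examples
#' fx <- exampleNetwork("C07277")
#' rankClasses(pathwayLikelihood(fx$network, fx$labels, "C07277"), "C07277")
#' @export
rankClasses <- function(values, query = NA_character_) {
  if (length(values) != 11)
    stop("a likelihood vector has exactly 11 entries")
  if (!is.null(names(values)) && !identical(names(values), .classTags()))
    stop("likelihood vector names must be M1..M11 in order")
  if (any(values < 0)) stop("likelihoods are non-negative")
  ord <- order(-values, seq_len(11))
  RankedPrediction(query, .classTags()[ord], values[ord])
}

#' Predict the top pathway classes of a query node
#'
#' Convenience wrapper: compute the likelihood vector, rank all 11
#' classes, and truncate to the first \code{top} positions.
#'
#' @inheritParams pathwayLikelihood
#' @param top number of leading positions to keep, in 1..11.
#' @return A [RankedPrediction] with \code{top} positions (likelihoods are
#'   reported alongside the classes for transparency).
#' @examples
#' fx <- exampleNetwork("C07277")
#' predictPathways(fx$network, fx$labels, "YLL058W", top = 2)
#' @export
predictPathways <- function(network, labels, node, top = 11) {
  if (length(top) != 1 || is.na(top) || top != round(top) ||
      top < 1 || top > 11)
    stop("'top' must be an integer in 1..11")
  rp <- rankClasses(pathwayLikelihood(network, labels, node),
                    toupper(node))
  RankedPrediction(rp@query, rp@order[seq_len(top)],
                   rp@values[seq_len(top)])
}
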