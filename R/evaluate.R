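.resolveSubset <- function(network, labels, subset) {
  ids <- intersect(nodeIds(network), nodeIds(labels))
  if (is.null(subset) || identical(subset, "all")) return(ids)
  if (length(subset) == 1 && subset %in% c("compounds", "enzymes")) {
    want <- sub("s$", "", subset)
    return(ids[nodeKinds(labels)[ids] == want])
  }
  subset <- toupper(subset)
  unknown <- setdiff(subset, ids)
  if (length(unknown))
    stop("subset node not in the labeled network: ", unknown[1])
  ids[ids %in% subset]
}

#' Leave-one-out jackknife predictions
#'
#' Ranks the 11 pathway classes for every evaluated sample with its own
#' labels withheld; the labels of all other samples remain available.
#' Because a node is never its own neighbor and [pathwayLikelihood()]
#' consults only neighbor labels, leaving the sample's labels out is exact
#' rather than approximate: each sample gets a unique, deterministic
#' predicted ranking.
#'
#' @param network a [HybridNetwork].
#' @param labels a [LabelTable].
#' @param subset \code{NULL} or \code{"all"} for every labeled network
#'   node, \code{"compounds"} / \code{"enzymes"}, or a character vector of
#'   node ids.
#' @return Named list of [RankedPrediction] objects, one per evaluated
#'   sample.
#' @seealso [evaluateNetwork()] for the full report.
#' @export
jackknife <- function(network, labels, subset = NULL) {
  ids <- .resolveSubset(network, labels, subset)
  L <- likelihoodMatrix(network, labels, ids)
  out <- lapply(seq_along(ids), function(i)
    rankClasses(L[i, ], ids[i]))
  stats::setNames(out, ids)
}

.rankingMatrix <- function(results) {
  if (length(results) == 0)
    return(matrix(character(), nrow = 0, ncol = 11))
  t(vapply(results, function(r) r@order, character(11)))
}

.correctnessMatrix <- function(results, labels) {
  m <- membershipMatrix(labels)
  ranks <- .rankingMatrix(results)
  ids <- vapply(results, queryId, "")
  correct <- matrix(FALSE, nrow = length(results), ncol = 11,
                    dimnames = list(ids, NULL))
  for (i in seq_along(results))
    correct[i, ] <- m[ids[i], ][ranks[i, ]]
  correct
}

#' Ordered prediction accuracies
#'
#' For each order \eqn{j}, \eqn{ACC_j = CM_j / N}: the fraction of
#' evaluated samples whose \eqn{j}-th ranked class is one of their true
#' classes (any-match: with multi-label samples, a rank position is
#' correct if it hits any true class). Every sample counts in the
#' denominator at every order, including samples whose likelihood vector
#' has fewer positive entries — the full-ranking convention under which
#' high-order accuracies can be nonzero.
#'
#' @param results named list of [RankedPrediction]s, e.g. from
#'   [jackknife()].
#' @param labels the [LabelTable] providing the true classes.
#' @return Numeric vector \code{ACC_1..ACC_11}, with the correct counts
#'   \eqn{CM_j} in attribute \code{"correctCounts"} and \eqn{N} in
#'   attribute \code{"nSamples"}.
#' @export
orderedAccuracy <- function(results, labels) {
  n <- length(results)
  if (n == 0) stop("no prediction results to evaluate")
  correct <- .correctnessMatrix(results, labels)
  cm <- as.integer(colSums(correct))
  structure(stats::setNames(cm / n, paste0("ACC_", 1:11)),
            correctCounts = cm, nSamples = n)
}

#' Coverage of true classes within the top-m predictions
#'
#' \eqn{L_m = \sum_i S_{i,m} / \sum_i N_i}, where \eqn{S_{i,m}} is the
#' number of sample \eqn{i}'s true classes found among its first \eqn{m}
#' ranked classes and \eqn{N_i} its number of true classes. When \code{m}
#' is omitted it defaults to \eqn{\lceil M \rceil}, the ceiling of the
#' average label count over the evaluated samples. With full rankings
#' \eqn{L_{11} = 1} always.
#'
#' @inheritParams orderedAccuracy
#' @param m rank depth in 1..11, or \code{NULL} for \eqn{\lceil M \rceil}.
#' @return The coverage fraction, with attribute \code{"m"}.
#' @export
coverage <- function(results, labels, m = NULL) {
  if (length(results) == 0) stop("no prediction results to evaluate")
  ids <- vapply(results, queryId, "")
  if (is.null(m)) {
    m <- averageLabelCount(labels, ids)$mCeiling
  } else if (length(m) != 1 || is.na(m) || m != round(m) || m < 1 || m > 11)
    stop("'m' must be an integer in 1..11")
  correct <- .correctnessMatrix(results, labels)
  sim <- rowSums(correct[, seq_len(m), drop = FALSE])
  ni <- labelCounts(labels)[ids]
  structure(sum(sim) / sum(ni), m = as.integer(m))
}

#' Average number of pathway classes per sample
#'
#' \eqn{M = \sum_i N_i / N} over the evaluated samples, kept as an exact
#' integer ratio alongside its decimal value and ceiling (the default
#' rank depth for [coverage()]).
#'
#' @param labels a [LabelTable].
#' @param subset \code{NULL} for all labeled nodes, \code{"compounds"} /
#'   \code{"enzymes"}, or a character vector of node ids.
#' @return List with \code{M} (numeric), \code{numerator} and
#'   \code{denominator} (integers \eqn{\sum_i N_i} and \eqn{N}) and
#'   \code{mCeiling}.
#' @examples
#' lt <- LabelTable(c("C00001", "C00002"), list("M1", c("M2", "M5")))
#' averageLabelCount(lt)
#' @export
averageLabelCount <- function(labels, subset = NULL) {
  ids <- nodeIds(labels)
  if (!is.null(subset)) {
    if (length(subset) == 1 && subset %in% c("compounds", "enzymes", "all")) {
      if (subset != "all") {
        want <- sub("s$", "", subset)
        ids <- ids[nodeKinds(labels)[ids] == want]
      }
    } else {
      subset <- toupper(subset)
      unknown <- setdiff(subset, ids)
      if (length(unknown)) stop("unlabeled node in subset: ", unknown[1])
      ids <- ids[ids %in% subset]
    }
  }
  if (length(ids) == 0) stop("empty sample subset")
  ni <- labelCounts(labels)[ids]
  num <- sum(ni)
  den <- length(ids)
  list(M = num / den, numerator = as.integer(num),
       denominator = as.integer(den),
       mCeiling = as.integer(ceiling(num / den)))
}

#' Random-guess success baseline
#'
#' With an average of \eqn{M} true classes per sample out of 11, a
#' uniformly random first guess succeeds with probability \eqn{M/11} —
#' the baseline the jackknife accuracies are compared against.
#'
#' @param M average label count, in \eqn{[1, 11]}.
#' @return The fraction \eqn{M/11}.
#' @examples
#' randomGuessRate(1.37)  # ~0.1245
#' @export
randomGuessRate <- function(M) {
  if (!is.numeric(M) || any(is.na(M)) || any(M < 1) || any(M > 11))
    stop("'M' must lie in [1, 11]")
  M / 11
}

#' Full jackknife evaluation of a labeled network
#'
#' Runs [jackknife()] and assembles ordered accuracies, coverage, average
#' label count and the random-guess baseline into one
#' [EvaluationReport].
#'
#' @inheritParams jackknife
#' @param m rank depth for the coverage statistic, or \code{NULL} for
#'   \eqn{\lceil M \rceil}.
#' @return An [EvaluationReport].
#' @examples
#' fx <- exampleNetwork("C07277")
#' evaluateNetwork(fx$network, fx$labels, subset = c("C07277", "YLL058W"))
#' @export
evaluateNetwork <- function(network, labels, subset = NULL, m = NULL) {
  results <- jackknife(network, labels, subset)
  if (length(results) == 0) stop("no labeled samples to evaluate")
  ids <- names(results)
  acc <- orderedAccuracy(results, labels)
  alc <- averageLabelCount(labels, ids)
  cov <- coverage(results, labels, m)
  memb <- membershipMatrix(labels)
  perSample <- data.frame(
    node = ids,
    kind = nodeKinds(labels)[ids],
    trueClasses = vapply(ids, function(i)
      paste(colnames(memb)[memb[i, ]], collapse = ","), ""),
    rankedClasses = vapply(results, function(r)
      paste(r@order, collapse = ","), ""),
    likelihoods = vapply(results, function(r)
      paste(r@values, collapse = ","), ""),
    firstOrderCorrect = vapply(ids, function(i)
      memb[i, results[[i]]@order[1]], NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
  methods::new("EvaluationReport",
               orderedAccuracy = as.numeric(acc),
               correctCounts = attr(acc, "correctCounts"),
               nSamples = length(ids),
               coverage = as.numeric(cov),
               mUsed = attr(cov, "m"),
               avgLabels = alc$M,
               labelTotal = alc$numerator,
               randomGuess = randomGuessRate(alc$M),
               perSample = perSample)
}
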