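#' Confidence-score contribution curves
#'
#' For each interaction kind (\code{cc}, \code{cp}, \code{pp}) and each
#' integer threshold \eqn{k} in \eqn{[1, 999]}, computes
#' \deqn{R_k = IM_k / I_k,}
#' where \eqn{I_k} is the number of interactions of that kind with
#' confidence score at least \eqn{k} and \eqn{IM_k} the number of those
#' whose two endpoints share at least one pathway class. \eqn{R_k}
#' quantifies how much the interactions at or above score \eqn{k}
#' contribute to correct guilt-by-association prediction; on the real
#' yeast network the \code{cp} and \code{pp} curves rise with \eqn{k}.
#'
#' @param network a [HybridNetwork].
#' @param labels a [LabelTable]; edges with an unlabeled endpoint are
#'   excluded from the tally (the loader drops them anyway).
#' @return data.frame with columns \code{kind}, \code{k}, \code{I}
#'   (\eqn{I_k}), \code{IM} (\eqn{IM_k}) and \code{R} (\eqn{R_k};
#'   \code{NA} where \eqn{I_k = 0}). 999 rows per kind.
#' @export
contributionCurves <- function(network, labels) {
  ed <- edgeTable(network)
  m <- membershipMatrix(labels)
  ia <- match(ed$a, rownames(m))
  ib <- match(ed$b, rownames(m))
  keep <- !is.na(ia) & !is.na(ib)
  ed <- ed[keep, , drop = FALSE]
  concordant <- rowSums(m[ia[keep], , drop = FALSE] &
                        m[ib[keep], , drop = FALSE]) > 0
  out <- lapply(.edgeKinds, function(kd) {
    sel <- ed$kind == kd
    # I_k = #{score >= k}: suffix sums of the score histogram
    histAll <- tabulate(ed$score[sel], nbins = 999)
    histCon <- tabulate(ed$score[sel & concordant], nbins = 999)
    I <- rev(cumsum(rev(histAll)))
    IM <- rev(cumsum(rev(histCon)))
    data.frame(kind = kd, k = 1:999, I = I, IM = IM,
               R = ifelse(I > 0, IM / I, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-class likelihood terms of one query: for class j, the scores of the
# neighbors carrying class j (the summands of F(s, M_j)).
.likelihoodTerms <- function(network, labels, node) {
  nb <- neighbors(network, node)
  m <- membershipMatrix(labels)
  idx <- match(nb$id, rownames(m))
  hit <- !is.na(idx)
  nb <- nb[hit, , drop = FALSE]
  idx <- idx[hit]
  lapply(.classTags(), function(tag) nb$score[m[idx, tag]])
}

#' Diagnose first-order misclassifications
#'
#' For every evaluated sample whose first-order predicted class is not
#' among its true classes, compares the likelihood sum terms (the
#' per-neighbor score contributions) of the predicted class against those
#' of the true classes, under two situations:
#' \describe{
#'   \item{situation 1}{the predicted class's terms exceed those of
#'     \emph{every} true class;}
#'   \item{situation 2}{the same restricted to high-confidence terms, i.e.
#'     scores strictly greater than \code{threshold} (default 700, the
#'     conventional STRING/STITCH high-confidence cutoff).}
#' }
#' "Exceed" is measured either as the \emph{number} of terms
#' (\code{interpretation = "count"}, the default) or their \emph{total}
#' (\code{"sum"}); the interpretation used is recorded in the output. A
#' sample fitting either situation drew more (or heavier) evidence toward
#' the wrong class than toward its own, so the miss is explained by the
#' neighborhood rather than by the method's ranking step.
#'
#' @param results named list of [RankedPrediction]s from [jackknife()].
#' @param network the [HybridNetwork] the results came from.
#' @param labels the [LabelTable] with the true classes.
#' @param threshold high-confidence score cutoff for situation 2
#'   (terms must be strictly greater).
#' @param interpretation \code{"count"} or \code{"sum"}.
#' @return List with \code{perSample} (data.frame: one row per
#'   misclassified sample, its predicted and true classes, term
#'   statistics and the two situation flags), \code{summary} (fractions
#'   of misclassified samples fitting situation 1, situation 2, at least
#'   one), \code{threshold} and \code{interpretation}.
#' @examples
#' fx <- exampleNetwork("C00439")
#' res <- jackknife(fx$network, fx$labels, subset = "C00439")
#' diagnoseMisclassified(res, fx$network, fx$labels)$perSample
#' @export
diagnoseMisclassified <- function(results, network, labels,
                                  threshold = 700,
                                  interpretation = c("count", "sum")) {
  interpretation <- match.arg(interpretation)
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold != round(threshold) || threshold < 0 || threshold > 999)
    stop("'threshold' must be an integer in [0, 999]")
  memb <- membershipMatrix(labels)
  rows <- list()
  for (id in names(results)) {
    rp <- results[[id]]
    trueTags <- colnames(memb)[memb[id, ]]
    first <- rp@order[1]
    if (first %in% trueTags) next
    terms <- .likelihoodTerms(network, labels, id)
    names(terms) <- .classTags()
    stat <- function(x) switch(interpretation,
                               count = length(x), sum = sum(x))
    statHigh <- function(x) stat(x[x > threshold])
    predStat <- stat(terms[[first]])
    predHigh <- statHigh(terms[[first]])
    trueStat <- vapply(terms[trueTags], stat, numeric(1))
    trueHigh <- vapply(terms[trueTags], statHigh, numeric(1))
    rows[[id]] <- data.frame(
      node = id,
      predictedFirst = first,
      trueClasses = paste(trueTags, collapse = ","),
      predictedTerms = predStat,
      maxTrueTerms = max(trueStat),
      predictedHighTerms = predHigh,
      maxTrueHighTerms = max(trueHigh),
      fitsSituation1 = all(predStat > trueStat),
      fitsSituation2 = all(predHigh > trueHigh),
      stringsAsFactors = FALSE
    )
  }
  perSample <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(node = character(), predictedFirst = character(),
                    trueClasses = character(), predictedTerms = numeric(),
                    maxTrueTerms = numeric(), predictedHighTerms = numeric(),
                    maxTrueHighTerms = numeric(), fitsSituation1 = logical(),
                    fitsSituation2 = logical(), stringsAsFactors = FALSE)
  n <- nrow(perSample)
  summary <- data.frame(
    nMisclassified = n,
    fracSituation1 = if (n) mean(perSample$fitsSituation1) else NA_real_,
    fracSituation2 = if (n) mean(perSample$fitsSituation2) else NA_real_,
    fracEither = if (n) mean(perSample$fitsSituation1 |
                             perSample$fitsSituation2) else NA_real_
  )
  list(perSample = perSample, summary = summary,
       threshold = as.integer(threshold), interpretation = interpretation)
}

#' Distribution of misclassified samples over pathway classes
#'
#' Counts, for each pathway class, the first-order-misclassified samples
#' that truly belong to it. A multi-label misclassified sample increments
#' every one of its true classes, so the column total can exceed the
#' number of misclassified samples.
#'
#' @inheritParams diagnoseMisclassified
#' @return data.frame with columns \code{tag}, \code{name} and
#'   \code{nMisclassified}, plus attribute \code{"nSamples"} (number of
#'   distinct misclassified samples).
#' @export
misclassifiedByClass <- function(results, labels) {
  memb <- membershipMatrix(labels)
  counts <- stats::setNames(integer(11), .classTags())
  nMis <- 0L
  for (id in names(results)) {
    trueTags <- colnames(memb)[memb[id, ]]
    if (results[[id]]@order[1] %in% trueTags) next
    nMis <- nMis + 1L
    counts[trueTags] <- counts[trueTags] + 1L
  }
  out <- cbind(pathwayClasses()[, c("tag", "name")],
               nMisclassified = as.integer(counts))
  rownames(out) <- NULL
  structure(out, nSamples = nMis)
}
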