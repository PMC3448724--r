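#' The 11 major KEGG metabolic pathway classes
#'
#' The fixed label vocabulary of the predictor: the 11 top-level KEGG
#' metabolic pathway categories, tagged \code{M1..M11}. The index/tag/name
#' mapping is a fixed bijection; every likelihood vector, ranking and
#' evaluation statistic in this package is expressed over these classes in
#' this order.
#'
#' @return A data.frame with columns \code{index} (1..11), \code{tag}
#'   (\code{"M1".."M11"}) and \code{name} (canonical class name).
#' @examples
#' pathwayClasses()
#' @export
pathwayClasses <- function() {
  data.frame(
    index = 1:11,
    tag = paste0("M", 1:11),
    name = c(
      "Carbohydrate Metabolism",
      "Energy Metabolism",
      "Lipid Metabolism",
      "Nucleotide Metabolism",
      "Amino Acid Metabolism",
      "Metabolism of Other Amino Acids",
      "Glycan Biosynthesis and Metabolism",
      "Metabolism of Cofactors and Vitamins",
      "Metabolism of Terpenoids and Polyketides",
      "Biosynthesis of Other Secondary Metabolites",
      "Xenobiotics Biodegradation and Metabolism"
    ),
    stringsAsFactors = FALSE
  )
}

.classTags <- function() paste0("M", 1:11)
.nodeKinds <- c("compound", "enzyme")
.edgeKinds <- c("cc", "cp", "pp")

#' Yeast benchmark label-count summary
#'
#' Printed per-dataset totals for the yeast benchmark the method was
#' developed on: 3,348 small molecules carrying 3,844 pathway-class
#' memberships and 654 enzymes carrying 898. These counts drive the average
#' label count \eqn{M}, the top-\eqn{m} cutoff \eqn{m = \lceil M \rceil} and
#' the random-guess baseline \eqn{M/11} (see
#' \code{\link{averageLabelCount}}, \code{\link{randomGuessRate}}).
#'
#' @return A data.frame with one row per dataset (\code{compounds},
#'   \code{enzymes}, \code{all}) and columns \code{nSamples} (dataset size
#'   \eqn{N}) and \code{nLabels} (total class memberships
#'   \eqn{\sum_i N_i}).
#' @examples
#' benchmarkLabelStats()
#' @export
benchmarkLabelStats <- function() {
  data.frame(
    dataset = c("compounds", "enzymes", "all"),
    nSamples = c(3348L, 654L, 4002L),
    nLabels = c(3844L, 898L, 4742L),
    stringsAsFactors = FALSE
  )
}

#' @rdname HybridNetwork
#' @export
setClass("HybridNetwork",
  representation(
    nodes = "data.frame",  # id, kind
    edges = "data.frame"   # a, b, score, kind; canonical a < b
  )
)

setValidity("HybridNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (!identical(names(nd), c("id", "kind")))
    msgs <- c(msgs, "nodes must have columns id, kind")
  if (!identical(names(ed), c("a", "b", "score", "kind")))
    msgs <- c(msgs, "edges must have columns a, b, score, kind")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicate node ids")
  if (any(!nzchar(nd$id))) msgs <- c(msgs, "empty node id")
  if (any(!nd$kind %in% .nodeKinds))
    msgs <- c(msgs, "node kind must be 'compound' or 'enzyme'")
  if (nrow(ed)) {
    if (any(ed$a == ed$b)) msgs <- c(msgs, "self-loop edge")
    if (!all(c(ed$a, ed$b) %in% nd$id))
      msgs <- c(msgs, "edge endpoint not a declared node")
    if (any(ed$score != round(ed$score)) ||
        any(ed$score < 1) || any(ed$score > 999))
      msgs <- c(msgs, "edge scores must be integers in [1, 999]")
    key <- paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate unordered edge pair")
    kindOf <- stats::setNames(nd$kind, nd$id)
    expect <- .pairEdgeKind(kindOf[ed$a], kindOf[ed$b])
    if (any(ed$kind != expect, na.rm = TRUE))
      msgs <- c(msgs, "edge kind inconsistent with endpoint kinds")
  }
  if (length(msgs)) msgs else TRUE
})

.pairEdgeKind <- function(kindA, kindB) {
  ifelse(kindA == "compound" & kindB == "compound", "cc",
    ifelse(kindA == "enzyme" & kindB == "enzyme", "pp", "cp"))
}

#' Hybrid chemical-protein interaction network
#'
#' An undirected, weighted graph whose nodes are small molecules
#' (compounds) and enzymes, and whose edges are chemical-chemical
#' (\code{cc}), chemical-protein (\code{cp}) or protein-protein (\code{pp})
#' interactions, each carrying an integer confidence score in
#' \eqn{[1, 999]}. An absent edge is equivalent to confidence 0. Edges are
#' stored once per unordered pair (canonically \code{a < b}); duplicate
#' input pairs are collapsed to their maximum score.
#'
#' @param nodes data.frame with columns \code{id} (unique, non-empty;
#'   uppercased) and \code{kind} (\code{"compound"} or \code{"enzyme"}).
#' @param edges data.frame with columns \code{a}, \code{b}, \code{score}
#'   and optionally \code{kind}; the kind is derived from the endpoint
#'   kinds and, if supplied, checked against them.
#' @return A \code{HybridNetwork} object.
#' @seealso [readHybridNetwork()], [neighbors()], [simulateHybridNetwork()]
#' @examples
#' nodes <- data.frame(id = c("C00001", "C00002", "YAL012W"),
#'                     kind = c("compound", "compound", "enzyme"))
#' edges <- data.frame(a = c("C00001", "C00001"),
#'                     b = c("C00002", "YAL012W"),
#'                     score = c(500L, 700L))
#' HybridNetwork(nodes, edges)
#' @export
HybridNetwork <- function(nodes = data.frame(id = character(),
                                             kind = character()),
                          edges = data.frame(a = character(),
                                             b = character(),
                                             score = integer())) {
  nodes <- data.frame(id = toupper(as.character(nodes$id)),
                      kind = as.character(nodes$kind),
                      stringsAsFactors = FALSE)
  a <- toupper(as.character(edges$a))
  b <- toupper(as.character(edges$b))
  score <- as.integer(edges$score)
  # canonical unordered orientation, then max-score dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    ord <- order(key, -score)
    keep <- ord[!duplicated(key[ord])]
    keep <- sort(keep)
    lo <- lo[keep]; hi <- hi[keep]; score <- score[keep]
  }
  kindOf <- stats::setNames(nodes$kind, nodes$id)
  ed <- data.frame(a = lo, b = hi, score = score,
                   kind = .pairEdgeKind(kindOf[lo], kindOf[hi]),
                   stringsAsFactors = FALSE)
  rownames(ed) <- NULL
  if (!is.null(edges$kind) && nrow(ed)) {
    given <- as.character(edges$kind)[keep]
    bad <- which(given != ed$kind)
    if (length(bad))
      stop("declared edge kind '", given[bad[1]], "' for pair (",
           ed$a[bad[1]], ", ", ed$b[bad[1]], ") does not match endpoint kinds")
  }
  methods::new("HybridNetwork", nodes = nodes, edges = ed)
}

#' @rdname LabelTable
#' @export
setClass("LabelTable",
  representation(
    membership = "matrix",  # logical, nodes x 11, rownames = ids
    kind = "character"      # named by node id
  )
)

setValidity("LabelTable", function(object) {
  m <- object@membership
  msgs <- character()
  if (!is.logical(m)) msgs <- c(msgs, "membership must be a logical matrix")
  if (ncol(m) != 11 || !identical(colnames(m), .classTags()))
    msgs <- c(msgs, "membership must have columns M1..M11")
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    msgs <- c(msgs, "membership rownames must be unique node ids")
  if (nrow(m) && any(rowSums(m) == 0))
    msgs <- c(msgs, "every labeled node must belong to >= 1 class")
  if (nrow(m) > 0 && !identical(names(object@kind), rownames(m)))
    msgs <- c(msgs, "kind must be named by the membership rownames")
  if (length(object@kind) && any(!object@kind %in% .nodeKinds))
    msgs <- c(msgs, "node kind must be 'compound' or 'enzyme'")
  if (length(msgs)) msgs else TRUE
})

#' Pathway-class label table
#'
#' Maps each node to its (non-empty) set of pathway classes, stored as the
#' 11-column 0/1 membership matrix over \code{M1..M11}; row \eqn{i}, column
#' \eqn{j} is 1 iff sample \eqn{i} belongs to class \eqn{M_j}.
#'
#' @param ids character vector of node ids (uppercased).
#' @param classes list (parallel to \code{ids}) of character vectors of
#'   class tags \code{"M1".."M11"}.
#' @param kind character vector of node kinds (\code{"compound"} or
#'   \code{"enzyme"}); inferred from the id with [inferNodeKind()] when
#'   missing.
#' @return A \code{LabelTable} object.
#' @examples
#' LabelTable(c("C00103", "YLL058W"),
#'            list(c("M1", "M9", "M10"), c("M2", "M5")))
#' @export
LabelTable <- function(ids = character(), classes = list(), kind = NULL) {
  ids <- toupper(as.character(ids))
  if (length(ids) != length(classes))
    stop("ids and classes must have the same length")
  if (is.null(kind)) kind <- inferNodeKind(ids)
  m <- matrix(FALSE, nrow = length(ids), ncol = 11,
              dimnames = list(ids, .classTags()))
  for (i in seq_along(ids)) {
    tags <- unique(as.character(classes[[i]]))
    bad <- setdiff(tags, .classTags())
    if (length(bad))
      stop("unknown pathway class tag '", bad[1], "' for node ", ids[i])
    m[i, tags] <- TRUE
  }
  methods::new("LabelTable", membership = m,
               kind = stats::setNames(as.character(kind), ids))
}

#' Infer node kind from its identifier
#'
#' KEGG compound ids are \code{C} followed by five digits; anything else is
#' taken to be an enzyme (e.g. a yeast ORF name such as \code{YLL058W}).
#' Used when an input file omits the kind column.
#'
#' @param ids character vector of node ids.
#' @return character vector, \code{"compound"} or \code{"enzyme"}.
#' @examples
#' inferNodeKind(c("C07277", "YLL058W"))
#' @export
inferNodeKind <- function(ids) {
  ifelse(grepl("^C[0-9]{5}$", toupper(ids)), "compound", "enzyme")
}

#' @rdname RankedPrediction
#' @export
setClass("RankedPrediction",
  representation(
    query = "character",
    order = "character",  # class tags, best first
    values = "numeric"    # likelihoods in that order
  )
)

setValidity("RankedPrediction", function(object) {
  msgs <- character()
  if (length(object@query) != 1) msgs <- c(msgs, "query must be length 1")
  if (length(object@order) != length(object@values))
    msgs <- c(msgs, "order and values must have the same length")
  if (length(object@order) > 11 || anyDuplicated(object@order) ||
      any(!object@order %in% .classTags()))
    msgs <- c(msgs, "order must be distinct class tags M1..M11")
  if (is.unsorted(rev(object@values)))
    msgs <- c(msgs, "values must be non-increasing")
  if (any(object@values < 0)) msgs <- c(msgs, "likelihoods are non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Ranked pathway-class prediction
#'
#' The full (or truncated) ranking of the 11 pathway classes for one query
#' node, by descending likelihood; position \eqn{k} holds the \eqn{k}-th
#' order predicted pathway class. Ties, including the all-zero tail, are
#' broken by ascending class index so the ranking is always a deterministic
#' permutation.
#'
#' @param query node id.
#' @param order character vector of class tags, best first.
#' @param values likelihoods in the same order (non-increasing).
#' @return A \code{RankedPrediction} object; coerce with
#'   \code{as.data.frame} for a \code{rank/class/likelihood} table.
#' @seealso [rankClasses()], [predictPathways()]
#' @export
RankedPrediction <- function(query, order, values) {
  methods::new("RankedPrediction", query = as.character(query),
               order = as.character(order), values = as.numeric(values))
}

#' @rdname EvaluationReport
#' @export
setClass("EvaluationReport",
  representation(
    orderedAccuracy = "numeric",   # ACC_1..ACC_11
    correctCounts = "integer",     # CM_1..CM_11
    nSamples = "integer",
    coverage = "numeric",          # L_m
    mUsed = "integer",
    avgLabels = "numeric",         # M
    labelTotal = "integer",        # sum_i N_i over evaluated samples
    randomGuess = "numeric",       # M / 11
    perSample = "data.frame"
  )
)

setValidity("EvaluationReport", function(object) {
  msgs <- character()
  if (length(object@orderedAccuracy) != 11 ||
      length(object@correctCounts) != 11)
    msgs <- c(msgs, "orderedAccuracy and correctCounts must have length 11")
  if (any(object@orderedAccuracy < 0) || any(object@orderedAccuracy > 1))
    msgs <- c(msgs, "accuracies must lie in [0, 1]")
  if (length(object@coverage) == 1 &&
      (object@coverage < 0 || object@coverage > 1))
    msgs <- c(msgs, "coverage must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
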