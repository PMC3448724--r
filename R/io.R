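#' Read a labeled hybrid network from edge and label TSV files
#'
#' The edge file has tab-separated columns \code{node_a}, \code{node_b},
#' \code{score} and optionally \code{kind} (\code{cc}/\code{cp}/\code{pp});
#' the label file has \code{node_id}, \code{kind}
#' (\code{compound}/\code{enzyme}; inferred from the id when the column is
#' absent) and \code{classes}, a comma-separated list of tags
#' \code{M1..M11}. Lines starting with \code{#} and blank lines are
#' ignored in both files. Node ids are uppercased.
#'
#' Every labeled node becomes a network node, including isolated ones.
#' Duplicate unordered edge pairs are collapsed to their maximum score.
#' Edges with an unlabeled endpoint are dropped with a message: an
#' unlabeled neighbor contributes zero to every class likelihood, so such
#' edges are inert for prediction.
#'
#' @param edgePath path to the edge TSV.
#' @param labelPath path to the label TSV.
#' @return A list with elements \code{network} ([HybridNetwork]),
#'   \code{labels} ([LabelTable]) and \code{droppedEdges} (number of edges
#'   removed because an endpoint had no label row).
#' @seealso [writeHybridNetwork()] for the inverse operation.
#' @export
readHybridNetwork <- function(edgePath, labelPath) {
  lab <- .readLabelFile(labelPath)
  ed <- .readEdgeFile(edgePath)

  labeled <- lab$ids
  keep <- ed$a %in% labeled & ed$b %in% labeled
  dropped <- sum(!keep)
  if (dropped > 0)
    message("dropped ", dropped,
            " edge(s) with an unlabeled endpoint (inert for prediction)")
  ed <- ed[keep, , drop = FALSE]

  nodes <- data.frame(id = lab$ids, kind = lab$kind,
                      stringsAsFactors = FALSE)
  net <- HybridNetwork(nodes, ed)
  labels <- LabelTable(lab$ids, lab$classes, lab$kind)
  list(network = net, labels = labels, droppedEdges = dropped)
}

.readTsvLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineNo = which(keep))
}

.readEdgeFile <- function(path) {
  tsv <- .readTsvLines(path)
  nf <- lengths(tsv$fields)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad))
    stop("malformed edge row at ", path, " line ", tsv$lineNo[bad[1]],
         ": expected 3 or 4 tab-separated fields, got ", nf[bad[1]])
  get <- function(i) vapply(tsv$fields, function(f) trimws(f[i]), "")
  n <- length(tsv$fields)
  if (n == 0)
    return(data.frame(a = character(), b = character(), score = integer(),
                      stringsAsFactors = FALSE))
  a <- toupper(get(1)); b <- toupper(get(2))
  rawScore <- get(3)
  score <- suppressWarnings(as.numeric(rawScore))
  bad <- which(is.na(score))
  if (length(bad))
    stop("non-numeric confidence score '", rawScore[bad[1]], "' at ",
         path, " line ", tsv$lineNo[bad[1]])
  bad <- which(score != round(score))
  if (length(bad))
    stop("fractional confidence score ", rawScore[bad[1]], " at ", path,
         " line ", tsv$lineNo[bad[1]], ": scores are integers in [1, 999]")
  bad <- which(score < 1 | score > 999)
  if (length(bad))
    stop("confidence score ", rawScore[bad[1]], " outside [1, 999] at ",
         path, " line ", tsv$lineNo[bad[1]])
  out <- data.frame(a = a, b = b, score = as.integer(score),
                    stringsAsFactors = FALSE)
  if (any(nf == 4L)) {
    kind <- ifelse(nf == 4L, tolower(get(4)), NA_character_)
    bad <- which(!is.na(kind) & !kind %in% .edgeKinds)
    if (length(bad))
      stop("unknown interaction kind '", kind[bad[1]], "' at ", path,
           " line ", tsv$lineNo[bad[1]])
    out$kind <- kind
  }
  out
}

.readLabelFile <- function(path) {
  tsv <- .readTsvLines(path)
  nf <- lengths(tsv$fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop("malformed label row at ", path, " line ", tsv$lineNo[bad[1]],
         ": expected node_id<TAB>kind<TAB>classes, got ", nf[bad[1]],
         " field(s)")
  n <- length(tsv$fields)
  if (n == 0)
    return(list(ids = character(), kind = character(), classes = list()))
  get <- function(i) vapply(tsv$fields, function(f) trimws(f[i]), "")
  ids <- toupper(get(1))
  # two-column dialect: node_id<TAB>classes, kind inferred from the id
  if (all(nf == 2L)) {
    kind <- inferNodeKind(ids)
    rawClasses <- get(2)
  } else {
    if (any(nf == 2L))
      stop("mixed 2- and 3-column label rows in ", path, " (first at line ",
           tsv$lineNo[which(nf == 2L)[1]], ")")
    kind <- tolower(get(2))
    bad <- which(!kind %in% .nodeKinds)
    if (length(bad))
      stop("unknown node kind '", kind[bad[1]], "' at ", path, " line ",
           tsv$lineNo[bad[1]])
    rawClasses <- get(3)
  }
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate label row for node ", ids[dup[1]], " at ", path,
         " line ", tsv$lineNo[dup[1]])
  classes <- strsplit(rawClasses, ",", fixed = TRUE)
  classes <- lapply(classes, function(x) unique(trimws(x)))
  for (i in seq_along(classes)) {
    cls <- classes[[i]]
    cls <- cls[nzchar(cls)]
    if (length(cls) == 0)
      stop("empty class list at ", path, " line ", tsv$lineNo[i])
    unknown <- setdiff(cls, .classTags())
    if (length(unknown))
      stop("unknown pathway class tag '", unknown[1], "' at ", path,
           " line ", tsv$lineNo[i])
    classes[[i]] <- cls
  }
  list(ids = ids, kind = kind, classes = classes)
}

#' Write a labeled hybrid network to edge and label TSV files
#'
#' Writes the same dialect that [readHybridNetwork()] reads, so a network
#' round-trips unchanged. A `#`-prefixed comment line documents the
#' columns.
#'
#' @param network a [HybridNetwork].
#' @param labels a [LabelTable] covering the network's nodes.
#' @param edgePath,labelPath output file paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
writeHybridNetwork <- function(network, labels, edgePath, labelPath) {
  ed <- edgeTable(network)
  edgeLines <- c("# node_a\tnode_b\tscore\tkind",
                 sprintf("%s\t%s\t%d\t%s", ed$a, ed$b, ed$score, ed$kind))
  writeLines(edgeLines, edgePath)

  m <- membershipMatrix(labels)
  tags <- apply(m, 1, function(r) paste(colnames(m)[r], collapse = ","))
  labelLines <- c("# node_id\tkind\tclasses",
                  sprintf("%s\t%s\t%s", rownames(m),
                          nodeKinds(labels)[rownames(m)], tags))
  writeLines(labelLines, labelPath)
  invisible(c(edgePath, labelPath))
}

#' Bundled worked-example subnetworks
#'
#' Two small curated subnetworks of the yeast chemical-protein interaction
#' network, shipped as plain TSV under \code{inst/extdata} and used
#' throughout the documentation and tests:
#' \describe{
#'   \item{\code{"C07277"}}{the 17 interactions around compound C07277
#'     (true class M9, Metabolism of Terpenoids and Polyketides) and enzyme
#'     YLL058W (true classes M2 and M5), with each partner's pathway
#'     classes. C07277 is a first-order miss (M1 outranks M9); YLL058W's
#'     top two predictions are exactly its two true classes.}
#'   \item{\code{"C00439"}}{the labeled interaction partners of compound
#'     C00439 (true class M5, Amino Acid Metabolism), a classic
#'     misclassification: the likelihood for M8 (10,115) exceeds that for
#'     its true class M5 (7,210).}
#' }
#'
#' @param name \code{"C07277"} or \code{"C00439"}.
#' @return A list with \code{network}, \code{labels} and
#'   \code{droppedEdges}, as from [readHybridNetwork()].
#' @examples
#' fx <- exampleNetwork("C07277")
#' pathwayLikelihood(fx$network, fx$labels, "C07277")
#' @export
exampleNetwork <- function(name = c("C07277", "C00439")) {
  name <- match.arg(name)
  stem <- switch(name, C07277 = "c07277_yll058w", C00439 = "c00439")
  edgePath <- system.file("extdata", paste0(stem, "_edges.tsv"),
                          package = "metPathNet", mustWork = TRUE)
  labelPath <- system.file("extdata", paste0(stem, "_labels.tsv"),
                           package = "metPathNet", mustWork = TRUE)
  readHybridNetwork(edgePath, labelPath)
}
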