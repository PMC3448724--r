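# Brute-force oracles, independent of the package's computation paths:
# plain double loops over the raw edge table and label sets.

classTags <- paste0("M", 1:11)

# F(s, M_j) by scanning every edge and every class
oracleLikelihood <- function(network, labels, s) {
  ed <- edgeTable(network)
  m <- membershipMatrix(labels)
  v <- setNames(numeric(11), classTags)
  for (r in seq_len(nrow(ed))) {
    other <- if (ed$a[r] == s) ed$b[r] else if (ed$b[r] == s) ed$a[r]
             else next
    if (!other %in% rownames(m)) next
    for (tag in classTags)
      if (m[other, tag]) v[tag] <- v[tag] + ed$score[r]
  }
  v
}

# neighbor set by linear scan over the edge list
oracleNeighbors <- function(network, s) {
  ed <- edgeTable(network)
  out <- character()
  for (r in seq_len(nrow(ed))) {
    if (ed$a[r] == s) out <- c(out, ed$b[r])
    if (ed$b[r] == s) out <- c(out, ed$a[r])
  }
  sort(out)
}

# ACC_1..ACC_11 by per-sample recount
oracleOrderedAccuracy <- function(results, labels) {
  m <- membershipMatrix(labels)
  cm <- numeric(11)
  for (rp in results) {
    trueTags <- classTags[m[queryId(rp), ]]
    for (j in 1:11)
      if (predictedOrder(rp)[j] %in% trueTags) cm[j] <- cm[j] + 1
  }
  cm / length(results)
}

# L_m by per-sample recount
oracleCoverage <- function(results, labels, m) {
  memb <- membershipMatrix(labels)
  hits <- 0; total <- 0
  for (rp in results) {
    trueTags <- classTags[memb[queryId(rp), ]]
    hits <- hits + length(intersect(predictedOrder(rp)[seq_len(m)],
                                    trueTags))
    total <- total + length(trueTags)
  }
  hits / total
}

# a small simulated network for property tests
smallSim <- function(seed, nCompounds = 40, nEnzymes = 10, ...) {
  simulateHybridNetwork(simulationConfig(nCompounds = nCompounds,
                                         nEnzymes = nEnzymes,
                                         seed = seed, ...))
}

# build a network + labels directly from parallel vectors
makeNet <- function(a, b, score, classes) {
  ids <- union(union(a, b), names(classes))
  nodes <- data.frame(id = ids, kind = inferNodeKind(ids))
  net <- HybridNetwork(nodes, data.frame(a = a, b = b, score = score))
  labels <- LabelTable(names(classes), unname(classes))
  list(network = net, labels = labels)
}

writeTempNetwork <- function(edgeLines, labelLines) {
  ep <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  lp <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  writeLines(edgeLines, ep)
  writeLines(labelLines, lp)
  list(edges = ep, labels = lp)
}
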