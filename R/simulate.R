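#' Configuration for the synthetic hybrid-network generator
#'
#' Describes a labeled hybrid network with controlled statistical
#' structure. The defaults emulate the gross statistics of the yeast
#' benchmark at reduced size: 400 nodes at a compound:enzyme ratio of
#' about 5:1, 11 classes, a cc:cp:pp interaction mix of 0.66/0.20/0.14,
#' a multi-label rate giving a mean label count near 1.18, and integer
#' scores in [1, 999] split at the conventional high-confidence cutoff
#' of 700.
#'
#' @param nCompounds,nEnzymes node counts per kind.
#' @param nClasses number of pathway classes in use (labels are drawn
#'   uniformly from \code{M1..M<nClasses>}); at most 11.
#' @param meanDegree target mean degree; the generator places
#'   \code{round(meanDegree * n / 2)} distinct edges.
#' @param homophily probability that an edge joins two nodes sharing at
#'   least one class (the guilt-by-association signal; 0 = labels carry
#'   no information, 1 = every interaction is within-class).
#' @param multiLabelRate probability that a node carries a second class.
#' @param scoreLow,scoreHigh integer score ranges (inclusive) within
#'   [1, 999] for low- and high-confidence interactions.
#' @param pHighGivenConcordant probability that a concordant
#'   (class-sharing) edge draws its score from \code{scoreHigh};
#'   discordant edges always draw from \code{scoreLow}. Coupling high
#'   scores to concordance gives synthetic contribution curves their
#'   rising shape.
#' @param kindMix named proportions of \code{cc}, \code{cp}, \code{pp}
#'   edges (summing to 1).
#' @param seed integer seed; the single source of randomness.
#' @return A validated list of class \code{"simulationConfig"}.
#' @seealso [simulateHybridNetwork()]
#' @export
simulationConfig <- function(nCompounds = 334, nEnzymes = 66,
                             nClasses = 11, meanDegree = 8,
                             homophily = 0.6, multiLabelRate = 0.18,
                             scoreLow = c(1, 699),
                             scoreHigh = c(700, 999),
                             pHighGivenConcordant = 0.7,
                             kindMix = c(cc = 0.66, cp = 0.20, pp = 0.14),
                             seed = 1) {
  cfg <- list(nCompounds = as.integer(nCompounds),
              nEnzymes = as.integer(nEnzymes),
              nClasses = as.integer(nClasses),
              meanDegree = meanDegree, homophily = homophily,
              multiLabelRate = multiLabelRate,
              scoreLow = as.integer(scoreLow),
              scoreHigh = as.integer(scoreHigh),
              pHighGivenConcordant = pHighGivenConcordant,
              kindMix = kindMix, seed = as.integer(seed))
  n <- cfg$nCompounds + cfg$nEnzymes
  if (n < 2) stop("need at least two nodes")
  if (cfg$nClasses < 1 || cfg$nClasses > 11)
    stop("nClasses must be in 1..11")
  if (cfg$meanDegree <= 0) stop("meanDegree must be positive")
  if (cfg$meanDegree >= n - 1)
    stop("infeasible meanDegree: must be < n - 1 = ", n - 1)
  for (p in c(cfg$homophily, cfg$multiLabelRate, cfg$pHighGivenConcordant))
    if (is.na(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]")
  for (r in list(cfg$scoreLow, cfg$scoreHigh))
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1 || r[2] > 999)
      stop("score ranges must be within [1, 999] with low <= high")
  if (!identical(sort(names(cfg$kindMix)), c("cc", "cp", "pp")))
    stop("kindMix must be named cc, cp, pp")
  if (any(cfg$kindMix < 0) || abs(sum(cfg$kindMix) - 1) > 1e-8)
    stop("kindMix proportions must be non-negative and sum to 1")
  class(cfg) <- "simulationConfig"
  cfg
}

# split m into integer kind counts proportional to the mix
.kindCounts <- function(m, mix) {
  mix <- mix[c("cc", "cp", "pp")]
  counts <- floor(m * mix)
  rem <- m - sum(counts)
  if (rem > 0) {
    extra <- order(m * mix - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Generate a synthetic labeled hybrid network
#'
#' Assigns each node one class uniformly at random (a distinct second
#' class with probability \code{multiLabelRate}), then places edges:
#' each edge's kind follows \code{kindMix}, and with probability
#' \code{homophily} the edge is required to join two nodes sharing a
#' class (rejection-sampled among kind-appropriate pairs, without
#' duplicates or self-loops). Scores are drawn uniformly from
#' \code{scoreHigh} with probability \code{pHighGivenConcordant} for
#' concordant edges and from \code{scoreLow} otherwise. The whole
#' construction is a deterministic function of the config (including its
#' seed).
#'
#' @param config a [simulationConfig()].
#' @return List with \code{network} ([HybridNetwork]), \code{labels}
#'   ([LabelTable]) and \code{info}: the config, the realized concordant
#'   edge fraction, and \code{skippedEdges}, the number of edges left
#'   unplaced because no unused pair of the drawn concordance existed
#'   (0 in ordinary regimes; can be large at extreme homophily, where the
#'   homophily contract takes precedence over the degree target).
#' @examples
#' sim <- simulateHybridNetwork(simulationConfig(nCompounds = 40,
#'                                               nEnzymes = 10, seed = 7))
#' sim$network
#' @export
simulateHybridNetwork <- function(config = simulationConfig()) {
  if (!inherits(config, "simulationConfig"))
    stop("'config' must come from simulationConfig()")
  set.seed(config$seed)
  nC <- config$nCompounds; nE <- config$nEnzymes
  n <- nC + nE
  ids <- c(sprintf("C9%04d", seq_len(nC)), sprintf("E%04d", seq_len(nE)))
  kind <- c(rep("compound", nC), rep("enzyme", nE))

  memb <- matrix(FALSE, n, 11, dimnames = list(ids, .classTags()))
  first <- sample.int(config$nClasses, n, replace = TRUE)
  memb[cbind(seq_len(n), first)] <- TRUE
  second <- stats::runif(n) < config$multiLabelRate
  if (config$nClasses > 1) {
    for (i in which(second)) {
      j <- sample.int(config$nClasses - 1, 1)
      if (j >= first[i]) j <- j + 1
      memb[i, j] <- TRUE
    }
  }

  m <- round(config$meanDegree * n / 2)
  counts <- .kindCounts(m, config$kindMix)
  avail <- c(cc = choose(nC, 2), cp = nC * nE, pp = choose(nE, 2))
  infeasible <- counts > avail[names(counts)]
  if (any(infeasible))
    stop("infeasible edge count for kind ",
         names(counts)[infeasible][1], ": need ",
         counts[infeasible][1], " distinct pairs, only ",
         avail[names(counts)][infeasible][1], " exist")

  compIdx <- seq_len(nC); enzIdx <- nC + seq_len(nE)
  used <- new.env(hash = TRUE, size = 2L * m)
  ea <- integer(m); eb <- integer(m); concord <- logical(m)
  e <- 0L; skipped <- 0L
  for (kd in c("cc", "cp", "pp")) {
    k <- counts[[kd]]
    if (k == 0) next
    poolA <- switch(kd, cc = compIdx, cp = compIdx, pp = enzIdx)
    poolB <- switch(kd, cc = compIdx, cp = enzIdx, pp = enzIdx)
    for (ii in seq_len(k)) {
      wantConcordant <- stats::runif(1) < config$homophily
      placed <- FALSE
      for (try in seq_len(2000L)) {
        a <- poolA[sample.int(length(poolA), 1)]
        b <- poolB[sample.int(length(poolB), 1)]
        if (a == b) next
        key <- paste0(min(a, b), ".", max(a, b))
        if (!is.null(used[[key]])) next
        isCon <- any(memb[a, ] & memb[b, ])
        if (isCon != wantConcordant) next
        used[[key]] <- TRUE
        e <- e + 1L; ea[e] <- a; eb[e] <- b; concord[e] <- isCon
        placed <- TRUE
        break
      }
      # no unused pair of the requested concordance found after the retry
      # budget: skip this edge rather than break the homophily contract
      # (at homophily 1 every placed edge must be concordant)
      if (!placed) skipped <- skipped + 1L
    }
  }
  ea <- ea[seq_len(e)]; eb <- eb[seq_len(e)]; concord <- concord[seq_len(e)]

  drawScore <- function(isCon) {
    rng <- if (isCon && stats::runif(1) < config$pHighGivenConcordant)
      config$scoreHigh else config$scoreLow
    rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
  }
  score <- vapply(concord, drawScore, integer(1))

  nodes <- data.frame(id = ids, kind = kind, stringsAsFactors = FALSE)
  edges <- data.frame(a = ids[ea], b = ids[eb], score = score,
                      stringsAsFactors = FALSE)
  network <- HybridNetwork(nodes, edges)
  classes <- lapply(seq_len(n), function(i) .classTags()[memb[i, ]])
  labels <- LabelTable(ids, classes, kind)
  list(network = network, labels = labels,
       info = list(config = config,
                   concordantFraction = if (e) mean(concord) else NA_real_,
                   skippedEdges = skipped))
}
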