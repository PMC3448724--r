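test_that("contribution curves count threshold exceedances exactly", {
  # 3 cc edges: scores 100 (concordant), 500 (discordant), 900 (concordant)
  net <- makeNet(
    a = c("C00001", "C00003", "C00005"),
    b = c("C00002", "C00004", "C00006"),
    score = c(100L, 500L, 900L),
    classes = list(C00001 = "M1", C00002 = "M1",
                   C00003 = "M2", C00004 = "M3",
                   C00005 = "M4", C00006 = "M4"))
  curves <- contributionCurves(net$network, net$labels)
  cc <- curves[curves$kind == "cc", ]
  expect_identical(cc$I[cc$k == 1], 3L)      # every score >= 1
  expect_equal(cc$R[cc$k == 1], 2 / 3)
  expect_equal(cc$R[cc$k == 501], 1)
  expect_identical(cc$I[cc$k == 901], 0L)
  expect_true(is.na(cc$R[cc$k == 901]))
  # the other kinds have no edges at all
  expect_true(all(curves$I[curves$kind != "cc"] == 0L))
})

test_that("I_k is non-increasing with IM_k <= I_k for every kind", {
  sim <- smallSim(seed = 31, nCompounds = 80, nEnzymes = 20)
  curves <- contributionCurves(sim$network, sim$labels)
  for (kd in c("cc", "cp", "pp")) {
    sub <- curves[curves$kind == kd, ]
    expect_true(all(diff(sub$I) <= 0))
    expect_true(all(sub$IM <= sub$I))
    expect_true(all(sub$IM >= 0))
    expect_identical(sub$I[1], sum(edgeTable(sim$network)$kind == kd))
    r <- sub$R[!is.na(sub$R)]
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("score-concordance coupling produces rising contribution curves", {
  # high scores only on concordant edges: R jumps to 1 past the split
  sim <- smallSim(seed = 32, nCompounds = 120, nEnzymes = 30,
                  scoreLow = c(1, 500), scoreHigh = c(701, 999),
                  pHighGivenConcordant = 1, homophily = 0.5)
  curves <- contributionCurves(sim$network, sim$labels)
  cc <- curves[curves$kind == "cc", ]
  expect_equal(cc$R[cc$k == 701], 1)
  expect_lt(cc$R[cc$k == 1], 1)
})

test_that("the C00439 worked example fits both misclassification situations", {
  fx <- exampleNetwork("C00439")
  res <- jackknife(fx$network, fx$labels, subset = "C00439")
  diag <- diagnoseMisclassified(res, fx$network, fx$labels)
  expect_identical(diag$interpretation, "count")
  expect_identical(diag$threshold, 700L)
  ps <- diag$perSample
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$predictedFirst, "M8")
  expect_identical(ps$trueClasses, "M5")
  # term counts straight off the partner lists: 14 for M8 vs 11 for M5,
  # of which 10 vs 6 exceed the 700 high-confidence cutoff
  expect_equal(ps$predictedTerms, 14)
  expect_equal(ps$maxTrueTerms, 11)
  expect_equal(ps$predictedHighTerms, 10)
  expect_equal(ps$maxTrueHighTerms, 6)
  expect_true(ps$fitsSituation1)
  expect_true(ps$fitsSituation2)
  expect_equal(diag$summary$fracEither, 1)

  # under the sum interpretation the totals are the printed likelihoods
  diagSum <- diagnoseMisclassified(res, fx$network, fx$labels,
                                   interpretation = "sum")
  expect_equal(diagSum$perSample$predictedTerms, 10115)
  expect_equal(diagSum$perSample$maxTrueTerms, 7210)
  expect_true(diagSum$perSample$fitsSituation1)
})

test_that("count and sum interpretations can disagree", {
  # predicted class: 2 terms of 700; true class: 3 terms of 100.
  # count: 2 > 3 fails and no term exceeds 700; sum: 1400 > 300 holds.
  net <- makeNet(
    a = c("Q1", "Q1", "Q1", "Q1", "Q1"),
    b = c("W1", "W2", "T1", "T2", "T3"),
    score = c(700L, 700L, 100L, 100L, 100L),
    classes = list(Q1 = "M1", W1 = "M2", W2 = "M2",
                   T1 = "M1", T2 = "M1", T3 = "M1"))
  res <- jackknife(net$network, net$labels, subset = "Q1")
  expect_identical(predictedOrder(res[["Q1"]])[1], "M2")
  byCount <- diagnoseMisclassified(res, net$network, net$labels)
  expect_false(byCount$perSample$fitsSituation1)
  expect_false(byCount$perSample$fitsSituation2)
  bySum <- diagnoseMisclassified(res, net$network, net$labels,
                                 interpretation = "sum")
  expect_true(bySum$perSample$fitsSituation1)
})

test_that("a multi-label sample must be beaten on every true class", {
  # true classes M1 (1 term of 100) and M3 (3 terms of 300); predicted
  # M2 (2 terms of 500) beats M1 on count but not M3
  net <- makeNet(
    a = rep("Q1", 6),
    b = c("W1", "W2", "T1", "U1", "U2", "U3"),
    score = c(500L, 500L, 100L, 300L, 300L, 300L),
    classes = list(Q1 = c("M1", "M3"), W1 = "M2", W2 = "M2",
                   T1 = "M1", U1 = "M3", U2 = "M3", U3 = "M3"))
  res <- jackknife(net$network, net$labels, subset = "Q1")
  expect_identical(predictedOrder(res[["Q1"]])[1], "M2")
  diag <- diagnoseMisclassified(res, net$network, net$labels)
  expect_false(diag$perSample$fitsSituation1)  # 2 > 3 fails for M3
})

test_that("misclassification tallies per class follow footnote semantics", {
  sim <- smallSim(seed = 33, homophily = 1, multiLabelRate = 0)
  deg <- table(c(edgeTable(sim$network)$a, edgeTable(sim$network)$b))
  connected <- nodeIds(sim$network)[nodeIds(sim$network) %in% names(deg)]
  res <- jackknife(sim$network, sim$labels, subset = connected)
  allCorrect <- misclassifiedByClass(res, sim$labels)
  expect_true(all(allCorrect$nMisclassified == 0L))

  # one misclassified multi-label sample increments both its classes
  net <- makeNet(
    a = c("Q1", "Q1"), b = c("W1", "W2"), score = c(500L, 400L),
    classes = list(Q1 = c("M2", "M5"), W1 = "M1", W2 = "M2"))
  res1 <- jackknife(net$network, net$labels, subset = "Q1")
  tally <- misclassifiedByClass(res1, net$labels)
  expect_identical(tally$nMisclassified[tally$tag %in% c("M2", "M5")],
                   c(1L, 1L))
  expect_identical(sum(tally$nMisclassified), 2L)
  expect_identical(attr(tally, "nSamples"), 1L)
})

test_that("diagnosis summary fractions recount against a brute-force scan", {
  sim <- simulateHybridNetwork(simulationConfig(nCompounds = 120,
                                                nEnzymes = 30,
                                                homophily = 0.4,
                                                seed = 34))
  res <- jackknife(sim$network, sim$labels)
  diag <- diagnoseMisclassified(res, sim$network, sim$labels)
  memb <- membershipMatrix(sim$labels)
  missIds <- names(Filter(function(rp)
    !predictedOrder(rp)[1] %in% classTags[memb[queryId(rp), ]], res))
  expect_setequal(diag$perSample$node, missIds)
  expect_identical(attr(misclassifiedByClass(res, sim$labels), "nSamples"),
                   length(missIds))
  # per-class tally recount
  expected <- setNames(integer(11), classTags)
  for (id in missIds) {
    tags <- classTags[memb[id, ]]
    expected[tags] <- expected[tags] + 1L
  }
  expect_identical(misclassifiedByClass(res, sim$labels)$nMisclassified,
                   unname(expected))
  s <- diag$summary
  expect_true(all(unlist(s[, -1]) >= 0 & unlist(s[, -1]) <= 1))
  expect_gte(s$fracEither, max(s$fracSituation1, s$fracSituation2))
})
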