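test_that("jackknife on the worked example: C07277 misses, YLL058W hits", {
  fx <- exampleNetwork("C07277")
  res <- jackknife(fx$network, fx$labels,
                   subset = c("C07277", "YLL058W"))
  expect_identical(predictedOrder(res[["C07277"]])[1], "M1")
  expect_false("M1" %in% nodeClasses(fx$labels, "C07277"))
  expect_identical(predictedOrder(res[["YLL058W"]])[1], "M5")
  expect_true(all(predictedOrder(res[["YLL058W"]])[1:2] %in%
                  nodeClasses(fx$labels, "YLL058W")))

  acc <- orderedAccuracy(res, fx$labels)
  expect_equal(unname(acc[1]), 0.5)   # YLL058W only
  expect_equal(unname(acc[2]), 1.0)   # C07277's M9 and YLL058W's M2
})

test_that("a labeled node with no labeled neighbors ranks M1..M11", {
  f <- writeTempNetwork("# empty", "SOLO\tenzyme\tM7")
  loaded <- readHybridNetwork(f$edges, f$labels)
  res <- jackknife(loaded$network, loaded$labels)
  expect_identical(predictedOrder(res[["SOLO"]]), paste0("M", 1:11))
  expect_true(all(likelihoodValues(res[["SOLO"]]) == 0))
})

test_that("ordered accuracy counts any-match hits per rank position", {
  # 4 single-label samples: 3 correct at rank 1, 1 correct at rank 2
  classes <- list(Q1 = "M1", Q2 = "M1", Q3 = "M1", Q4 = "M2",
                  N1 = "M1", N2 = "M2")
  net <- makeNet(
    a = c("Q1", "Q2", "Q3", "Q4", "Q4"),
    b = c("N1", "N1", "N1", "N1", "N2"),
    score = c(500L, 500L, 500L, 500L, 400L),
    classes = classes)
  res <- jackknife(net$network, net$labels,
                   subset = c("Q1", "Q2", "Q3", "Q4"))
  acc <- orderedAccuracy(res, net$labels)
  expect_equal(as.numeric(acc[1:3]), c(0.75, 0.25, 0))
  expect_identical(attr(acc, "correctCounts")[1:2], c(3L, 1L))
  # recount oracle agrees
  expect_equal(as.numeric(acc), oracleOrderedAccuracy(res, net$labels))
})

test_that("every sample single-labeled and rank-1 correct: ACC = (1,0,...)", {
  sim <- smallSim(seed = 21, homophily = 1, multiLabelRate = 0)
  deg <- table(c(edgeTable(sim$network)$a, edgeTable(sim$network)$b))
  connected <- nodeIds(sim$network)[nodeIds(sim$network) %in% names(deg)]
  res <- jackknife(sim$network, sim$labels, subset = connected)
  acc <- orderedAccuracy(res, sim$labels)
  expect_equal(as.numeric(acc), c(1, rep(0, 10)))
})

test_that("coverage matches hand counts and defaults to m = ceiling(M)", {
  fx <- exampleNetwork("C07277")
  res <- jackknife(fx$network, fx$labels,
                   subset = c("C07277", "YLL058W"))
  # YLL058W-shaped case: true {M2,M5}, top-2 = (M5,M2)
  l2 <- coverage(res["YLL058W"], fx$labels, m = 2)
  expect_equal(as.numeric(l2), 1)

  # both samples: N_i = 1 + 2; hits in top-2: M9 (rank 2) + M5, M2
  expect_equal(as.numeric(coverage(res, fx$labels, m = 2)), 3 / 3)
  expect_equal(as.numeric(coverage(res, fx$labels, m = 1)), 1 / 3)

  # default m: average label count (1+2)/2 = 1.5 -> ceiling 2
  auto <- coverage(res, fx$labels)
  expect_identical(attr(auto, "m"), 2L)
  expect_error(coverage(res, fx$labels, m = 0), "1..11")
  expect_error(coverage(res, fx$labels, m = 12), "1..11")
})

test_that("coverage is non-decreasing in m and reaches 1 at m = 11", {
  sim <- smallSim(seed = 22, nCompounds = 80, nEnzymes = 20)
  res <- jackknife(sim$network, sim$labels)
  lm <- vapply(1:11, function(m)
    as.numeric(coverage(res, sim$labels, m)), numeric(1))
  expect_true(all(diff(lm) >= 0))
  expect_equal(lm[11], 1)
  # recount oracle at a middle depth
  expect_equal(lm[3], oracleCoverage(res, sim$labels, 3))
})

test_that("accuracy and coverage equal brute-force recounts on a benchmark", {
  sim <- simulateHybridNetwork(simulationConfig(nCompounds = 167,
                                                nEnzymes = 33, seed = 42))
  res <- jackknife(sim$network, sim$labels)
  acc <- orderedAccuracy(res, sim$labels)
  expect_equal(as.numeric(acc), oracleOrderedAccuracy(res, sim$labels))
  cov <- coverage(res, sim$labels)
  expect_equal(as.numeric(cov),
               oracleCoverage(res, sim$labels, attr(cov, "m")))
  # each true label matches at most one rank position
  expect_lte(sum(attr(acc, "correctCounts")),
             sum(labelCounts(sim$labels)))
})

test_that("average label count is an exact ratio with its ceiling", {
  lt <- LabelTable(c("A1", "B1", "C00001"),
                   list(c("M1", "M2"), "M3", c("M4", "M5", "M6")))
  alc <- averageLabelCount(lt)
  expect_identical(alc$numerator, 6L)
  expect_identical(alc$denominator, 3L)
  expect_equal(alc$M, 2)
  expect_identical(alc$mCeiling, 2L)

  single <- LabelTable(c("A1", "B1"), list("M1", "M2"))
  expect_equal(averageLabelCount(single)$M, 1)
  expect_error(averageLabelCount(single, subset = character(0)),
               "empty")

  # kind-restricted subsets
  mixed <- LabelTable(c("C00001", "C00002", "YAL012W"),
                      list(c("M1", "M2"), "M1", c("M1", "M2", "M3")))
  expect_equal(averageLabelCount(mixed, "compounds")$M, 1.5)
  expect_equal(averageLabelCount(mixed, "enzymes")$M, 3)
})

test_that("random-guess baseline is M/11 and rejects impossible M", {
  expect_equal(randomGuessRate(11), 1)
  expect_equal(randomGuessRate(1.37), 1.37 / 11)
  expect_error(randomGuessRate(0.5), "\\[1, 11\\]")
  expect_error(randomGuessRate(12), "\\[1, 11\\]")
})

test_that("evaluateNetwork assembles a consistent report", {
  sim <- smallSim(seed = 23)
  rep <- evaluateNetwork(sim$network, sim$labels)
  expect_s4_class(rep, "EvaluationReport")
  expect_identical(rep@nSamples, numNodes(sim$network))
  acc <- orderedAccuracyValues(rep)
  res <- jackknife(sim$network, sim$labels)
  expect_equal(unname(acc), unname(orderedAccuracy(res, sim$labels)),
               ignore_attr = TRUE)
  ps <- perSampleResults(rep)
  expect_identical(nrow(ps), rep@nSamples)
  expect_equal(mean(ps$firstOrderCorrect), unname(acc[1]))
  expect_equal(rep@randomGuess, rep@avgLabels / 11)
  # subset filters by kind
  repC <- evaluateNetwork(sim$network, sim$labels, subset = "compounds")
  expect_true(all(perSampleResults(repC)$kind == "compound"))
})
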