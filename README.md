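# metPathNet

Multi-label prediction of the 11 major KEGG metabolic pathway classes for
small molecules and enzymes, from a hybrid chemical–protein interaction
network.

## The problem and the method

Determining which metabolic pathways a compound or an enzyme participates
in is a first step in understanding a metabolic pathway system, and many
molecules participate in more than one. `metPathNet` implements a
guilt-by-association ranker for this multi-label problem, built on the
observation that interacting chemicals and proteins tend to share
biological function.

The data model is a **hybrid network**: nodes are small molecules
(compounds) and enzymes; edges are chemical–chemical (`cc`),
chemical–protein (`cp`) or protein–protein (`pp`) interactions, each
weighted by an integer confidence score `Q(·,·) ∈ [1, 999]` (as in
STITCH/STRING exports; an absent interaction has score 0). Each training
node carries a non-empty subset of the 11 pathway classes `M1..M11`
(Carbohydrate Metabolism, Energy Metabolism, ..., Xenobiotics
Biodegradation and Metabolism).

For a query node *s* with neighbor set *N(s)*, the likelihood that *s*
belongs to class *M_j* is the neighbor-weighted vote

    F(s, M_j) = Σ_{t ∈ N(s)} Q(s, t) · [ M_j ∈ labels(t) ]

and the prediction is the full ranking of all 11 classes by descending
`F` (ties broken by ascending class index): the top class is the 1st-order
predicted pathway class, the next the 2nd-order, and so on. The query's
own labels are never used, so leave-one-out (jackknife) evaluation is
exact.

Evaluation machinery included:

* **Ordered accuracies** `ACC_j = CM_j / N` — the fraction of samples whose
  *j*-th ranked class is one of their true classes.
* **Coverage** `L_m = Σ_i S_{i,m} / Σ_i N_i` — the fraction of all true
  class memberships recovered within each sample's top-*m* predictions,
  with *m* defaulting to the ceiling of the average label count
  `M = Σ_i N_i / N`; `M/11` is the random-guess baseline.
* **Contribution curves** `R_k = IM_k / I_k` per interaction kind — among
  edges with score ≥ *k*, the fraction joining two nodes that share a
  class.
* **Misclassification diagnosis** — for first-order misses, whether the
  wrong class simply attracted more (or more high-confidence, score > 700)
  likelihood terms than every true class.
* A **synthetic-network generator** with controlled homophily, score
  model, kind mix and multi-label rate, so the whole pipeline is testable
  without any database download.

## Worked example

Two curated subnetworks of the yeast interaction network ship with the
package. Enzyme YLL058W truly belongs to M2 (Energy Metabolism) and M5
(Amino Acid Metabolism):

```r
library(metPathNet)
fx <- exampleNetwork("C07277")
predictPathways(fx$network, fx$labels, "YLL058W", top = 4)
#> RankedPrediction for YLL058W
#>  rank class likelihood
#>     1    M5       4621
#>     2    M2       4042
#>     3    M6       1800
#>     4    M1        900
```

Its two true classes are exactly the two top-ranked predictions; the
likelihoods are the sums of the confidence scores of its partners carrying
each class (e.g. 4621 = 900+900+317+900+900+463+241 over its seven
M5-labeled partners). Compound C07277 in the same fixture is a documented
first-order miss (M1 outranks its true class M9), and
`exampleNetwork("C00439")` reproduces the classic misclassification where
M8 accumulates likelihood 10115 against 7210 for the true class M5.

A full synthetic benchmark, end to end:

```r
sim <- simulateHybridNetwork(simulationConfig(seed = 1))
evaluateNetwork(sim$network, sim$labels)
#> EvaluationReport over 400 samples
#>   average label count M = 1.1825 (473/400), ceiling 2
#>   random-guess baseline M/11 = 10.75%
#>   coverage L_2 = 93.45%
#>   ordered accuracies ACC_1..ACC_11 (%):
#>     93.00 17.50 3.25 1.25 1.50 0.25 0.25 0.75 0.00 0.00 0.50
```

With the default homophily of 0.6 the first-order accuracy (93%) towers
over the 10.75% random-guess baseline, and 93.45% of all true class
memberships are covered by the top-2 predictions — the qualitative
behaviour the method is designed to exhibit when interactions are
informative about shared pathways.

The same functionality is available from the shell via the installed
`exec/metPathNet` script (`predict`, `jackknife`, `score-curves`,
`diagnose`, `simulate`, `fixtures` subcommands); every run writes a
key-value manifest with input digests, parameters and seed.

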