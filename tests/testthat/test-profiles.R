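test_that("tool profiles encode the documented method combinations", {
  p <- toolProfile("precrec")
  expect_equal(methodOf(p)@noTies, "discrete_expectation")
  expect_equal(methodOf(p)@ties, "discrete_expectation")
  expect_equal(methodOf(p)@startPolicy, "segment_limit")
  expect_length(issueFlags(p), 0L)

  p <- toolProfile("PRROC-continuous")
  expect_equal(methodOf(p)@noTies, "continuous_expectation")
  expect_equal(methodOf(p)@ties, "continuous_expectation")
  expect_length(issueFlags(p), 0L)

  p <- toolProfile("PerfMeas")
  expect_equal(methodOf(p)@tiePolicy, "input_order")
  expect_equal(methodOf(p)@endPolicy, "truncate_at_last_distinct")
  expect_setequal(issueFlags(p), c(3L, 4L))

  # aliases and case-insensitivity
  expect_equal(profileName(toolProfile("sklearn-ap")), "scikit-learn-AP")
  expect_equal(profileName(toolProfile("weka")), "Weka")

  expect_error(toolProfile("foo"), class = "prcaudit_profile_error")

  expect_length(listToolProfiles(), 13L)
  # flag consistency: issue 4 (input-order ties) iff tie policy is input_order;
  # issue 2 iff the curve start is forced to (0,1)
  for (nm in listToolProfiles()) {
    p <- toolProfile(nm)
    expect_equal(4L %in% issueFlags(p),
                 methodOf(p)@tiePolicy == "input_order", info = nm)
    expect_equal(2L %in% issueFlags(p),
                 methodOf(p)@startPolicy == "fixed_0_1", info = nm)
    expect_equal(1L %in% issueFlags(p),
                 methodOf(p)@ties == "linear" &&
                   methodOf(p)@tiePolicy == "group", info = nm)
  }
})

test_that("compareMethods reports values, distinct count and spread", {
  ct <- compareMethods(constClassifier(3, 2),
                       c("scikit-learn-AP", "PRROC-continuous",
                         "scikit-learn-PR"))
  v <- as.numeric(comparisonValues(ct))
  expect_equal(v, c(0.6, 0.6, 0.8), tolerance = 1e-12)
  expect_equal(unname(distinctValues(ct)), 2L)
  expect_equal(unname(valueSpread(ct)), 0.2, tolerance = 1e-12)

  # a single profile trivially has zero spread
  ct <- compareMethods(d1(), "precrec")
  expect_equal(unname(valueSpread(ct)), 0)

  # on tie-free data, profiles differing only in their ties connector agree
  ct <- compareMethods(d1(), c("PRROC-discrete", "Weka", "TorchEval"))
  v <- comparisonValues(ct)
  expect_equal(v[, "Weka"], v[, "TorchEval"])
})

test_that("rankClassifiers exposes rank flips between profiles", {
  tieHeavy <- tieBlockFixture(list(c(3, 2)))
  tieFree <- tieBlockFixture(list(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0)))
  ct <- rankClassifiers(list(X = tieHeavy, Y = tieFree),
                        c("scikit-learn-PR", "Weka"))
  r <- rankMatrix(ct)
  # linear ties + forced start put the tie-heavy classifier first; the step
  # method reverses the order
  expect_equal(r["X", "scikit-learn-PR"], 1)
  expect_equal(r["X", "Weka"], 2)
  expect_false(all(r[, 1] == r[, 2]))

  # one classifier dominating under every profile keeps identical columns
  good <- scoredLabels(c(9, 8, 7, 2, 1), c(1, 1, 1, 0, 0))
  bad <- scoredLabels(c(9, 8, 7, 2, 1), c(0, 0, 1, 1, 1))
  ct <- rankClassifiers(list(good = good, bad = bad), "all")
  r <- rankMatrix(ct)
  expect_true(all(r["good", ] == 1))
  expect_true(all(r["bad", ] == 2))

  # correlation matrix of a single profile is the 1x1 identity
  ct <- rankClassifiers(list(good = good, bad = bad), "Weka")
  expect_equal(profileCorrelations(ct), matrix(1, 1, 1,
               dimnames = list("Weka", "Weka")))
})

test_that("auditScores quantifies tie, start and order susceptibility", {
  # tie-free data: no tie fraction, no order sensitivity
  rep1 <- auditScores(d1(), nShuffles = 20, seed = 1)
  expect_equal(rep1@tieFraction, 0)
  expect_equal(rep1@orderSensitivity, 0)

  # constant classifier: the documented 0.2 inflation
  rep2 <- auditScores(constClassifier(3, 2), nShuffles = 50, seed = 1)
  expect_equal(rep2@tieFraction, 1)
  expect_equal(rep2@inflation, 0.2, tolerance = 1e-12)
  expect_gt(rep2@orderSensitivity, 0)

  # all-positive data: every AUPRC is 1, all deltas vanish
  rep3 <- auditScores(scoredLabels(c(1, 1, 2), c(1, 1, 1)),
                      nShuffles = 10, seed = 1)
  expect_true(all(rep3@values == 1))
  expect_equal(rep3@inflation, 0)
  expect_equal(rep3@startEffect, 0)
  expect_equal(rep3@orderSensitivity, 0)

  # audits are reproducible given the seed
  rep4 <- auditScores(constClassifier(3, 2), nShuffles = 50, seed = 1)
  expect_identical(rep4@values, rep2@values)

  lst <- auditAsList(rep2)
  expect_named(lst, c("tie_fraction", "inflation", "start_effect",
                      "order_sensitivity", "n_shuffles", "values"))
})

test_that("profiles without the input-order flag are row-order invariant", {
  x <- tieBlockFixture(list(c(1, 0), c(2, 3), c(1, 1), c(0, 2)))
  set.seed(99)
  invariant <- setdiff(listToolProfiles(), "PerfMeas")
  ref <- vapply(invariant,
                function(nm) auprcValue(auprc(x, methodOf(toolProfile(nm)))),
                numeric(1))
  perfRef <- auprcValue(auprc(x, methodOf(toolProfile("PerfMeas"))))
  perfSeen <- perfRef
  for (i in 1:20) {
    o <- sample.int(length(x))
    shuf <- scoredLabels(scores(x)[o], labels(x)[o])
    vals <- vapply(invariant,
                   function(nm) auprcValue(auprc(shuf, methodOf(toolProfile(nm)))),
                   numeric(1))
    expect_identical(vals, ref)
    perfSeen <- c(perfSeen, auprcValue(auprc(shuf, methodOf(toolProfile("PerfMeas")))))
  }
  expect_gt(max(perfSeen) - min(perfSeen), 0)
})
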