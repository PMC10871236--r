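test_that("prcCurve emits the expected vertices", {
  cv <- as.data.frame(prcCurve(d1(), methodSpec("line", "linear")))
  expect_equal(cv$recall, c(0, 1/3, 2/3, 2/3, 1, 1))
  expect_equal(cv$precision, c(1, 1, 1, 2/3, 3/4, 3/5))
  expect_equal(cv$kind, c("start", rep("anchor", 4), "end"))

  # constant classifier under the continuous expectation: flat at prevalence
  cv <- as.data.frame(prcCurve(constClassifier(3, 2),
                               methodSpec(ties = "continuous_expectation")))
  expect_equal(cv$recall[1], 0)
  expect_true(all(abs(cv$precision - 0.6) < 1e-12))
  expect_equal(max(cv$recall), 1)

  # forced (0,1) start with a straight chord to the single anchor
  cv <- as.data.frame(prcCurve(constClassifier(3, 2),
                               methodSpec("line", "linear", "fixed_0_1")))
  expect_equal(cv$recall, c(0, 1))
  expect_equal(cv$precision, c(1, 0.6))
})

test_that("auprc reproduces the hand-computed areas on the reference data", {
  expect_equal(auprcValue(auprc(d1(), methodSpec("line", "linear"))), 65 / 72)
  expect_equal(auprcValue(auprc(d1(), methodSpec("step", "step"))), 11 / 12)
  expect_equal(auprcValue(auprc(d1(), methodSpec("continuous_expectation",
                                                 "continuous_expectation"))),
               2 / 3 + (1 - log(4 / 3)) / 3)
  # constant classifier: expectation methods give prevalence, the forced
  # (0,1) linear start gives the inflated trapezoid
  expect_equal(auprcValue(auprc(constClassifier(3, 2))), 0.6,
               tolerance = 1e-12)
  expect_equal(averagePrecision(constClassifier(3, 2)), 0.6)
  expect_equal(auprcValue(auprc(constClassifier(3, 2),
                                methodSpec("line", "linear", "fixed_0_1"))),
               0.8)
})

test_that("averagePrecision is the (step, step) spec and behaves at the limits", {
  expect_equal(averagePrecision(d1()),
               auprcValue(auprc(d1(), methodSpec("step", "step"))))
  separated <- scoredLabels(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))
  expect_equal(averagePrecision(separated), 1)
  expect_equal(averagePrecision(constClassifier(4, 6)), 0.4)
})

test_that("baselineAuprc is the prevalence", {
  expect_equal(baselineAuprc(1, 1), 0.5)
  expect_equal(round(baselineAuprc(32, 42), 3), 0.432)
  expect_equal(round(baselineAuprc(4012, 274380), 3), 0.014)
  expect_error(baselineAuprc(0, 10), class = "prcaudit_no_positives_error")
})

test_that("auroc matches the worked example and its invariances", {
  expect_equal(auroc(d1()), 5 / 6)
  expect_equal(auroc(constClassifier(3, 2)), 0.5)
  separated <- scoredLabels(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))
  expect_equal(auroc(separated), 1)
  expect_error(auroc(scoredLabels(c(1, 2), c(1, 1))),
               class = "prcaudit_no_negatives_error")

  # invariant under strictly monotone score transformations
  set.seed(42)
  for (i in 1:20) {
    x <- randomScored(sample(4:20, 1), withTies = TRUE)
    y <- scoredLabels(exp(2 * scores(x)) - 1, labels(x))
    expect_identical(auroc(y), auroc(x))
  }
})

test_that("the ties connector is irrelevant on tie-free data", {
  for (noTies in c("line", "discrete_expectation",
                   "continuous_expectation", "step")) {
    vals <- vapply(c("linear", "discrete_expectation",
                     "continuous_expectation", "step"),
                   function(t) auprcValue(auprc(d1(), methodSpec(noTies, t))),
                   numeric(1))
    expect_true(all(vals == vals[1]))
  }
})

test_that("raising a positive's score never lowers AP on tie-free data", {
  set.seed(7)
  for (i in 1:40) {
    x <- randomScored(sample(5:15, 1), withTies = FALSE)
    pos <- which(labels(x) == 1L)
    j <- pos[sample.int(length(pos), 1)]
    s <- scores(x)
    s[j] <- s[j] + stats::runif(1, 0, 1)
    expect_gte(averagePrecision(scoredLabels(s, labels(x))),
               averagePrecision(x) - 1e-12)
  }
})

test_that("with tie groups, promoting a positive can lower AP", {
  # pulling one positive out of a large all-positive tie block leaves it as
  # a lone low-precision anchor just below the top negatives; the recall it
  # covers was previously covered at the block's higher precision
  lab <- c(0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 1, 1, 1, 0, 1)
  s <- c(1, 0.25, 0.75, 0.25, 0.5, 0.25, 0, 0, 1, 0.5, 0.75, 0, 0.75, 1, 0.75)
  before <- averagePrecision(scoredLabels(s, lab))
  s[11] <- 0.9
  after <- averagePrecision(scoredLabels(s, lab))
  expect_equal(before, 0.5919642857142857, tolerance = 1e-12)
  expect_lt(after, before)
})

test_that("start and end policies change value and raise warnings", {
  res <- auprc(constClassifier(3, 2), methodSpec("line", "linear", "fixed_0_1"))
  expect_match(issueWarnings(res), "forced to \\(0, 1\\)", all = FALSE)
  expect_match(issueWarnings(res), "linear interpolation", all = FALSE)

  # truncation drops the final anchor's segment; pick data whose last
  # segment gains recall so the loss is visible
  dTrunc <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 0, 1))
  full <- auprcValue(auprc(dTrunc, methodSpec("step", "step")))
  res <- auprc(dTrunc, methodSpec("step", "step",
                                  endPolicy = "truncate_at_last_distinct"))
  expect_match(issueWarnings(res), "truncated", all = FALSE)
  expect_lt(auprcValue(res), full)
  cv <- prcCurve(dTrunc, methodSpec("step", "step",
                                    endPolicy = "truncate_at_last_distinct"))
  expect_lt(max(recall(cv)), 1)

  # skipping the zero-recall region drops the first segment's area
  res <- auprc(d1(), methodSpec("line", "linear", "first_anchor"))
  expect_equal(auprcValue(res), 65 / 72 - 1 / 3)
})

test_that("data without negatives give AUPRC 1 with a warning", {
  res <- auprc(scoredLabels(c(3, 2, 1), c(1, 1, 1)))
  expect_equal(auprcValue(res), 1)
  expect_match(issueWarnings(res), "no negative", all = FALSE)
})

test_that("curve and result exports round-trip through files", {
  tf <- tempfile(fileext = ".tsv")
  writeCurve(prcCurve(d1(), methodSpec("line", "linear")), tf)
  cv <- utils::read.delim(tf)
  expect_equal(names(cv), c("recall", "precision", "kind"))
  expect_equal(nrow(cv), 6L)

  js <- jsonlite::fromJSON(resultToJSON(auprc(d1())))
  expect_equal(js$value, auprcValue(auprc(d1())))
  expect_equal(js$method$tie_policy, "group")
})
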