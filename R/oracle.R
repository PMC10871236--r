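# Brute-force reference implementations.  Deliberately simple and slow:
# they exist so the closed-form estimators can be checked against exhaustive
# enumeration, quadrature and pairwise counting.

#' Permutation average over the orderings of a tie block
#'
#' Considers a tie block of `b` positives and `c` negatives appended to a
#' fixed prefix with cumulative counts `(tpA, fpA)`, and averages over
#' orderings of the block's entities (all orderings equally probable):
#' the expected false-positive count at the moment the s-th positive of the
#' block is reached (s = 1..b), and the mean step-curve (Average Precision)
#' area of the block treating each entity as a distinct threshold.
#'
#' In exhaustive mode all `choose(b + c, c)` distinct label orderings are
#' enumerated; in sampled mode `nSamples` random orderings are drawn under
#' `seed`.
#'
#' The closed form of the combinatorial expectation is
#' `E[fp at tp = s] = fpA + s * c / (b + 1)`, which differs in the interior
#' from the linear-fp surrogate `fpA + s * c / b` used by
#' [expectationPrecision()]; both meet at the block boundary in the sense
#' that the full block always ends at `(tpA + b, fpA + c)`.
#'
#' @param b,c positive and negative counts of the tie block (`b >= 1`).
#' @param tpA,fpA cumulative counts of the prefix before the block.
#' @param P total positives of the whole data set (for the recall scale).
#' @param mode `"exhaustive"` (requires `choose(b + c, c) <= 1e5`) or
#'   `"sampled"`.
#' @param nSamples number of sampled orderings in sampled mode.
#' @param seed integer seed, required in sampled mode.
#' @return A list with `expected_fp_at_tp` (numeric, length `b`),
#'   `expected_step_auprc` (mean block AP area, on the recall scale of `P`),
#'   and `n_orderings`.
#' @examples
#' permutationAverage(1, 1, 0, 0, P = 1)$expected_fp_at_tp   # 0.5
#' @export
permutationAverage <- function(b, c, tpA = 0L, fpA = 0L, P = tpA + b,
                               mode = c("exhaustive", "sampled"),
                               nSamples = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(b >= 1L, c >= 0L, tpA >= 0L, fpA >= 0L, P >= tpA + b)
  n <- b + c

  orderings <- if (mode == "exhaustive") {
    if (choose(n, c) > 1e5)
      .prcStop("prcaudit_oracle_error",
               "too many orderings for exhaustive enumeration")
    if (c == 0L) {
      list(rep(1L, b))
    } else {
      # each ordering = positions of the negative labels
      apply(utils::combn(n, c), 2L, function(negAt) {
        lab <- rep(1L, n); lab[negAt] <- 0L; lab
      }, simplify = FALSE)
    }
  } else {
    if (is.null(seed))
      .prcStop("prcaudit_oracle_error", "sampled mode requires a seed")
    .withSeed(seed, {
      replicate(nSamples, sample(rep(c(1L, 0L), c(b, c))), simplify = FALSE)
    })
  }

  fpAt <- matrix(0, nrow = length(orderings), ncol = b)
  ap <- numeric(length(orderings))
  for (i in seq_along(orderings)) {
    lab <- orderings[[i]]
    tp <- tpA + cumsum(lab == 1L)
    fp <- fpA + cumsum(lab == 0L)
    fpAt[i, ] <- fp[lab == 1L]
    # step-curve area of the block: one rectangle per entity-threshold
    ap[i] <- sum((lab == 1L) / P * tp / (tp + fp))
  }
  list(expected_fp_at_tp = colMeans(fpAt),
       expected_step_auprc = mean(ap),
       n_orderings = length(orderings))
}

#' Numeric quadrature of the expectation curve over one segment
#'
#' Composite midpoint/trapezoid quadrature of [expectationPrecision()] over
#' recall, used as an independent check of the closed form in
#' [continuousSegmentArea()].  The default `"simpson"` rule combines the two
#' as (2 midpoint + trapezoid) / 3.
#'
#' @inheritParams discreteExpectationVertices
#' @param nSteps number of panels (>= 10).
#' @param rule `"simpson"`, `"midpoint"` or `"trapezoid"`.
#' @return numeric scalar area on the recall scale.
#' @examples
#' quadratureSegmentArea(2, 1, 3, 1, P = 3, nSteps = 1000)
#' @export
quadratureSegmentArea <- function(tpA, fpA, tpB, fpB, P, nSteps = 10000L,
                                  rule = c("simpson", "midpoint", "trapezoid")) {
  rule <- match.arg(rule)
  stopifnot(nSteps >= 10L)
  dtp <- tpB - tpA
  if (dtp == 0) return(0)
  h <- dtp / nSteps
  edges <- seq(0, dtp, length.out = nSteps + 1L)
  mids <- (edges[-1L] + edges[-(nSteps + 1L)]) / 2
  f <- function(s) expectationPrecision(tpA, fpA, tpB, fpB, s)
  midSum <- h * sum(f(mids))
  if (rule == "midpoint") return(midSum / P)
  fe <- f(edges)
  trapSum <- h * (sum(fe) - (fe[1L] + fe[nSteps + 1L]) / 2)
  if (rule == "trapezoid") return(trapSum / P)
  (2 * midSum + trapSum) / 3 / P
}

#' Pairwise (Mann-Whitney) AUROC oracle
#'
#' Counts, over all positive/negative entity pairs, the fraction in which
#' the positive outscores the negative, tied pairs counting one half.  An
#' O(P x N) reference for [auroc()].
#'
#' @param data a [ScoredLabels-class] object.
#' @return numeric scalar in \[0, 1\].
#' @examples
#' d1 <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
#' mannWhitneyAuroc(d1)   # 5/6
#' @export
mannWhitneyAuroc <- function(data) {
  stopifnot(is(data, "ScoredLabels"))
  pos <- scores(data)[labels(data) == 1L]
  neg <- scores(data)[labels(data) == 0L]
  if (length(pos) == 0L) .stopNoPositives()
  if (length(neg) == 0L)
    .prcStop("prcaudit_no_negatives_error",
             "AUROC undefined: no negative entities")
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}
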