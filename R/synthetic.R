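#' Simulate score/label data with controllable imbalance, separation and ties
#'
#' Draws negative-class scores from a standard normal and positive-class
#' scores from a normal shifted up by `separation` (unit variance in both
#' classes; only the rank structure of the scores matters to every
#' estimator in this package).  Optionally quantizes the pooled scores into
#' `nLevels` equal-width bins (each score replaced by its bin midpoint),
#' emulating classifiers that emit discrete scores and thereby inducing tie
#' blocks.
#'
#' @param nPos number of positive entities (>= 1).
#' @param nNeg number of negative entities (>= 0).
#' @param separation location shift (in standard deviations) between the
#'   positive and negative score distributions; 0 = uninformative
#'   classifier.
#' @param nLevels positive integer number of discrete score levels, or
#'   `NULL` (default) for continuous scores.
#' @param seed integer seed; the same seed always reproduces the same data
#'   set, and the caller's RNG state is left untouched.
#' @return A [ScoredLabels-class] object (positives first in row order).
#' @examples
#' simulateScores(10, 90, separation = 1.5, nLevels = 5, seed = 42)
#' @export
simulateScores <- function(nPos, nNeg, separation = 1, nLevels = NULL,
                           seed = 1L) {
  stopifnot(nPos >= 1, nNeg >= 0, separation >= 0,
            is.null(nLevels) || nLevels >= 1)
  s <- .withSeed(seed, {
    c(stats::rnorm(nPos, mean = separation), stats::rnorm(nNeg, mean = 0))
  })
  if (!is.null(nLevels)) {
    rng <- range(s)
    if (rng[1] == rng[2]) {
      s <- rep(rng[1], length(s))
    } else {
      # equal-width bins over the pooled range, scores -> bin midpoints
      breaks <- seq(rng[1], rng[2], length.out = nLevels + 1L)
      bin <- pmin(findInterval(s, breaks, rightmost.closed = TRUE), nLevels)
      s <- (breaks[bin] + breaks[bin + 1L]) / 2
    }
  }
  scoredLabels(s, rep(c(1L, 0L), c(nPos, nNeg)))
}

#' Build a data set with an exact tie-group structure
#'
#' Constructs a [ScoredLabels-class] whose tie groups are exactly the
#' requested sequence of (positives, negatives) blocks at strictly
#' decreasing synthetic scores — useful for reproducing specific anchor
#' configurations (e.g. a clean prefix followed by one mixed tie block).
#'
#' @param blocks a list of length-2 vectors `c(n_pos, n_neg)`, ordered from
#'   the highest score down; each block must contain at least one entity.
#' @return A [ScoredLabels-class]; `groupTies()` of the result reproduces
#'   `blocks` exactly (scores are `k, k-1, ..., 1` for `k` blocks).
#' @examples
#' groupTies(tieBlockFixture(list(c(3, 0), c(5, 2), c(1, 1), c(0, 1))))
#' @export
tieBlockFixture <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  b <- vapply(blocks, function(x) as.integer(x[1]), integer(1))
  c_ <- vapply(blocks, function(x) as.integer(x[2]), integer(1))
  stopifnot(all(b >= 0L), all(c_ >= 0L), all(b + c_ >= 1L))
  k <- length(blocks)
  sc <- rep(seq(k, 1), b + c_)
  lab <- unlist(mapply(function(bi, ci) rep(c(1L, 0L), c(bi, ci)),
                       b, c_, SIMPLIFY = FALSE))
  scoredLabels(sc, lab)
}
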