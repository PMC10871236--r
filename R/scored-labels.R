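#' Construct a validated ScoredLabels object
#'
#' Validates and pairs per-entity classification scores with binary ground
#' truth labels.  Input row order is preserved; it matters only under the
#' input-order tie policy (see [methodSpec()]).
#'
#' @param scores numeric vector of finite classification scores (larger =
#'   more confidently positive).
#' @param labels vector of class labels; must contain only 0 and 1 (numeric,
#'   integer or logical), 1 marking the positive class.
#'
#' @return A [ScoredLabels-class] object.
#'
#' @details Each failure mode raises a distinct classed error
#'   (`prcaudit_length_error`, `prcaudit_label_error`, `prcaudit_score_error`,
#'   `prcaudit_empty_error`), all inheriting from `prcaudit_error`.
#'
#' @examples
#' sl <- scoredLabels(c(0.9, 0.1), c(1, 0))
#' nPos(sl)
#' nNeg(sl)
#' @export
scoredLabels <- function(scores, labels) {
  if (length(scores) == 0L && length(labels) == 0L) .stopEmpty()
  if (length(scores) != length(labels)) .stopLengthMismatch()
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1)))
    .stopNonBinary()
  if (!is.numeric(scores) || any(!is.finite(scores))) .stopNonFinite()
  new("ScoredLabels", scores = as.numeric(scores), labels = as.integer(labels))
}

#' @rdname prcaudit-generics
#' @export
setMethod("scores", "ScoredLabels", function(x) x@scores)

#' @rdname prcaudit-generics
#' @export
setMethod("labels", "ScoredLabels", function(object, ...) object@labels)

#' @rdname prcaudit-generics
#' @export
setMethod("nPos", "ScoredLabels", function(x) sum(x@labels == 1L))

#' @rdname prcaudit-generics
#' @export
setMethod("nNeg", "ScoredLabels", function(x) sum(x@labels == 0L))

setMethod("show", "ScoredLabels", function(object) {
  g <- groupTies(object)
  cat(sprintf("ScoredLabels: %d entities (%d positive, %d negative), %d tie group%s\n",
              length(object@scores), nPos(object), nNeg(object),
              nrow(g), if (nrow(g) == 1L) "" else "s"))
})

#' @describeIn scoredLabels number of entities.
#' @param x a `ScoredLabels` object.
#' @export
setMethod("length", "ScoredLabels", function(x) length(x@scores))

#' Group tied scores into tie groups
#'
#' Entities sharing exactly the same classification score form one tie group
#' and together define a single anchor point on the precision-recall curve.
#' Grouping uses exact floating-point equality; no epsilon tolerance is
#' applied (callers may pre-round scores if approximate grouping is wanted).
#'
#' @param x a [ScoredLabels-class] object.
#' @return A `data.frame` with one row per group, columns `score` (strictly
#'   decreasing), `n_pos` and `n_neg` (counts of positive and negative
#'   entities at that score).
#' @examples
#' groupTies(scoredLabels(c(0.7, 0.7, 0.2), c(1, 0, 1)))
#' @export
groupTies <- function(x) {
  stopifnot(is(x, "ScoredLabels"))
  s <- x@scores
  lab <- x@labels
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  lab <- lab[o]
  # run-length over the sorted scores: exact equality defines a group
  r <- rle(s)
  idx <- rep.int(seq_along(r$values), r$lengths)
  data.frame(score = r$values,
             n_pos = as.integer(tapply(lab == 1L, idx, sum)),
             n_neg = as.integer(tapply(lab == 0L, idx, sum)),
             row.names = NULL)
}
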