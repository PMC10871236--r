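#' Build the anchor-point path of a precision-recall curve
#'
#' Every distinct observed score is used as a threshold `t`; classifying all
#' entities with score >= t as positive yields cumulative true-positive and
#' false-positive counts, one anchor point per threshold.  Entities tied at
#' one score define a single anchor ("group" policy).  The alternative
#' "input_order" policy emulates tools that order tied entities by their
#' position in the input and then treat every entity as having a distinct
#' score, yielding one anchor per entity and an input-order-dependent path.
#'
#' @param x a [ScoredLabels-class] object, or (for `anchorPath` only) a
#'   `data.frame` of tie groups as returned by [groupTies()].
#' @param tiePolicy `"group"` (default) or `"input_order"`.
#' @return An [AnchorPath-class] object.
#' @examples
#' d1 <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
#' anchorPath(d1)
#' @export
anchorPath <- function(x, tiePolicy = c("group", "input_order")) {
  tiePolicy <- match.arg(tiePolicy)
  if (tiePolicy == "input_order") return(anchorPathInputOrder(x))
  groups <- if (is.data.frame(x)) x else groupTies(x)
  stopifnot(all(c("score", "n_pos", "n_neg") %in% names(groups)),
            nrow(groups) >= 1L)
  P <- sum(groups$n_pos)
  N <- sum(groups$n_neg)
  if (P < 1L) .stopNoPositives()
  new("AnchorPath",
      threshold = groups$score,
      tp = as.integer(cumsum(groups$n_pos)),
      fp = as.integer(cumsum(groups$n_neg)),
      P = as.integer(P), N = as.integer(N))
}

#' @rdname anchorPath
#' @export
anchorPathInputOrder <- function(x) {
  stopifnot(is(x, "ScoredLabels"))
  if (nPos(x) < 1L) .stopNoPositives()
  o <- order(x@scores, decreasing = TRUE)  # stable: input order kept in ties
  lab <- x@labels[o]
  new("AnchorPath",
      threshold = x@scores[o],
      tp = as.integer(cumsum(lab == 1L)),
      fp = as.integer(cumsum(lab == 0L)),
      P = as.integer(nPos(x)), N = as.integer(nNeg(x)))
}

#' @rdname prcaudit-generics
#' @export
setMethod("nPos", "AnchorPath", function(x) x@P)

#' @rdname prcaudit-generics
#' @export
setMethod("nNeg", "AnchorPath", function(x) x@N)

#' @rdname prcaudit-generics
#' @export
setMethod("recall", "AnchorPath", function(x) x@tp / x@P)

#' @rdname prcaudit-generics
#' @export
setMethod("precision", "AnchorPath", function(x) x@tp / (x@tp + x@fp))

#' @describeIn anchorPath number of anchor points.
#' @export
setMethod("length", "AnchorPath", function(x) length(x@tp))

setMethod("show", "AnchorPath", function(object) {
  cat(sprintf("AnchorPath: %d anchor points, P = %d, N = %d\n",
              length(object@tp), object@P, object@N))
  df <- as.data.frame(object)
  print(utils::head(df, 8L))
  if (nrow(df) > 8L) cat(sprintf("... and %d more\n", nrow(df) - 8L))
})

#' Coerce an AnchorPath to a data.frame
#'
#' @param x an [AnchorPath-class] object.
#' @param ... unused.
#' @return data.frame with columns threshold, tp, fp, recall, precision.
#' @exportS3Method base::as.data.frame
#' @export as.data.frame.AnchorPath
as.data.frame.AnchorPath <- function(x, ...) {
  data.frame(threshold = x@threshold, tp = x@tp, fp = x@fp,
             recall = x@tp / x@P, precision = x@tp / (x@tp + x@fp))
}
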