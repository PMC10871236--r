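#' Expected precision along a segment between two anchor points
#'
#' Between adjacent anchors A = (tp_A, fp_A) and B = (tp_B, fp_B) the
#' expectation interpolation assumes the false-positive count grows linearly
#' with the true-positive count, so after s additional true positives
#' (0 <= s <= dTP, dTP = tp_B - tp_A) the expected precision is
#' \deqn{p(s) = \frac{tp_A + s}{tp_A + s + fp_A + s\,\Delta FP/\Delta TP}.}
#' This is the interpolation underlying both the discrete (piece-wise linear)
#' and continuous expectation connectors.
#'
#' @param tpA,fpA cumulative counts at anchor A (the higher threshold).
#' @param tpB,fpB cumulative counts at anchor B; `tpB > tpA` is required.
#' @param s numeric vector of interpolation positions in `[0, tpB - tpA]`.
#' @return Numeric vector of precisions.  At `s = 0` with `tpA + fpA = 0`
#'   (the virtual origin) the continuity limit
#'   `dTP / (dTP + dFP)` is returned.
#' @examples
#' expectationPrecision(0, 0, 3, 2, 1.5)   # 0.6
#' expectationPrecision(2, 1, 3, 1, 0.5)   # 2.5/3.5
#' @export
expectationPrecision <- function(tpA, fpA, tpB, fpB, s) {
  dtp <- tpB - tpA
  dfp <- fpB - fpA
  if (dtp <= 0)
    .prcStop("prcaudit_segment_error",
             "expectation undefined on vertical segment (no change in tp)")
  if (any(s < 0 | s > dtp))
    .prcStop("prcaudit_range_error",
             sprintf("s must lie in [0, %g]", dtp))
  p <- (tpA + s) / (tpA + s + fpA + s * dfp / dtp)
  # continuity limit at the virtual origin (0,0): p -> dTP/(dTP+dFP)
  p[s == 0 & tpA + fpA == 0] <- dtp / (dtp + dfp)
  p
}

#' Interior vertices of the discrete expectation connector
#'
#' The discrete expectation method inserts interpolated points on the
#' expectation curve at integer (offset 1) or half-integer (offset 0.5)
#' true-positive increments and joins consecutive points by straight lines.
#' The half-integer offset is used between anchors one entity apart (no
#' ties); the integer offset across multi-entity tie blocks.
#'
#' @inheritParams expectationPrecision
#' @param P total number of positive entities (for the recall coordinate).
#' @param offset 0.5 or 1.0; vertices are placed at
#'   `s = offset, offset + 1, ... < tpB - tpA`.
#' @return data.frame with columns `recall`, `precision` (possibly 0 rows).
#' @examples
#' discreteExpectationVertices(0, 0, 3, 2, P = 3, offset = 1)
#' @export
discreteExpectationVertices <- function(tpA, fpA, tpB, fpB, P, offset = 0.5) {
  stopifnot(offset %in% c(0.5, 1.0))
  dtp <- tpB - tpA
  if (dtp <= 0)
    .prcStop("prcaudit_segment_error",
             "expectation undefined on vertical segment (no change in tp)")
  s <- seq(offset, dtp, by = 1)
  s <- s[s < dtp]
  if (length(s) == 0L)
    return(data.frame(recall = numeric(0), precision = numeric(0)))
  data.frame(recall = (tpA + s) / P,
             precision = expectationPrecision(tpA, fpA, tpB, fpB, s))
}

#' Segment areas under the four connectors
#'
#' Area contributed to the AUPRC by the segment between anchors A and B,
#' under each connection method:
#' \describe{
#'   \item{`continuousSegmentArea`}{the exact integral of the expectation
#'     curve [expectationPrecision()] over recall.  With
#'     `beta = 1 + dFP/dTP` and `C = tpA + fpA`, the closed form is
#'     `(1/P) * (dTP/beta + (tpA - C/beta) * (1/beta) * log((C + beta*dTP)/C))`,
#'     the log term dropping when its coefficient vanishes or `C = 0`.}
#'   \item{`linearSegmentArea`}{the trapezoid
#'     `(recallB - recallA) * (precisionA + precisionB)/2` under the straight
#'     chord from A to B.}
#'   \item{`stepSegmentArea`}{the rectangle
#'     `(recallB - recallA) * precisionB` of the step (Average Precision)
#'     connector.}
#'   \item{`discreteExpectationArea`}{the trapezoid sum over the chords
#'     through the [discreteExpectationVertices()] and the two anchors.}
#' }
#' Vertical segments (`tpB == tpA`, a pure precision drop at fixed recall)
#' contribute zero area under every method.
#'
#' @inheritParams discreteExpectationVertices
#' @param precisionA precision to use at the left endpoint; defaults to
#'   `tpA/(tpA+fpA)`, or the connector's continuity limit at the virtual
#'   origin.  Override (e.g. with 1) to emulate a forced (0, 1) curve start.
#' @return Numeric scalar area (already divided by P, i.e. on recall scale).
#' @examples
#' continuousSegmentArea(2, 1, 3, 1, P = 3)  # (1 - log(4/3))/3
#' linearSegmentArea(2, 1, 3, 1, P = 3)      # 17/72
#' stepSegmentArea(2, 1, 3, 1, P = 3)        # 1/4
#' @export
continuousSegmentArea <- function(tpA, fpA, tpB, fpB, P) {
  dtp <- tpB - tpA
  dfp <- fpB - fpA
  if (dtp == 0) return(0)
  beta <- 1 + dfp / dtp
  C <- tpA + fpA
  coef <- tpA - C / beta
  area <- dtp / beta
  if (C > 0 && coef != 0)
    area <- area + coef * log((C + beta * dtp) / C) / beta
  area / P
}

#' @rdname continuousSegmentArea
#' @export
linearSegmentArea <- function(tpA, fpA, tpB, fpB, P, precisionA = NULL) {
  dtp <- tpB - tpA
  if (dtp == 0) return(0)
  if (is.null(precisionA)) {
    precisionA <- if (tpA + fpA > 0) tpA / (tpA + fpA)
                  else dtp / (dtp + fpB - fpA)
  }
  precisionB <- tpB / (tpB + fpB)
  (dtp / P) * (precisionA + precisionB) / 2
}

#' @rdname continuousSegmentArea
#' @export
stepSegmentArea <- function(tpA, fpA, tpB, fpB, P) {
  dtp <- tpB - tpA
  if (dtp == 0) return(0)
  (dtp / P) * tpB / (tpB + fpB)
}

#' @rdname continuousSegmentArea
#' @param offset vertex spacing for the discrete expectation connector
#'   (0.5 between untied anchors, 1.0 across tie blocks).
#' @export
discreteExpectationArea <- function(tpA, fpA, tpB, fpB, P, offset = 0.5,
                                    precisionA = NULL) {
  dtp <- tpB - tpA
  if (dtp == 0) return(0)
  if (is.null(precisionA)) {
    precisionA <- if (tpA + fpA > 0) tpA / (tpA + fpA)
                  else dtp / (dtp + fpB - fpA)
  }
  v <- discreteExpectationVertices(tpA, fpA, tpB, fpB, P, offset)
  r <- c(tpA / P, v$recall, tpB / P)
  p <- c(precisionA, v$precision, tpB / (tpB + fpB))
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}
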