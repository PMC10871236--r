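#' Create a MethodSpec
#'
#' A MethodSpec pins down every choice that affects a PR curve and its area.
#' The default is the combination free of the known conceptual issues:
#' straight lines between untied anchors, the continuous expectation curve
#' across tie blocks, a zero-recall start vertex at the first segment's
#' precision limit, the full recall range, and grouped ties.
#'
#' @param noTies connector between anchors one entity apart: `"line"`,
#'   `"discrete_expectation"`, `"continuous_expectation"` or `"step"`.
#' @param ties connector across a multi-entity tie block: `"linear"`,
#'   `"discrete_expectation"`, `"continuous_expectation"` or `"step"`.
#' @param startPolicy `"segment_limit"` (zero-recall vertex at the first
#'   segment's precision limit), `"fixed_0_1"` (curve forced to start at
#'   (0, 1) — an emulation of issue-2 behaviour), or `"first_anchor"` (no
#'   zero-recall vertex; the area below the first anchor's recall is dropped,
#'   emulating incomplete curves).
#' @param endPolicy `"full_recall"` or `"truncate_at_last_distinct"` (drop
#'   the final anchor, so the curve stops short of recall 1).
#' @param tiePolicy `"group"` (tied entities form one anchor) or
#'   `"input_order"` (ties broken by input row order, one anchor per entity).
#' @return A [MethodSpec-class] object.
#' @examples
#' methodSpec()                       # the issue-free default
#' methodSpec("step", "step")         # Average Precision
#' @export
methodSpec <- function(noTies = "line",
                       ties = "continuous_expectation",
                       startPolicy = "segment_limit",
                       endPolicy = "full_recall",
                       tiePolicy = "group") {
  # accept the natural synonyms for the straight-chord connector
  if (identical(noTies, "linear")) noTies <- "line"
  if (identical(ties, "line")) ties <- "linear"
  new("MethodSpec", noTies = noTies, ties = ties,
      startPolicy = startPolicy, endPolicy = endPolicy, tiePolicy = tiePolicy)
}

setMethod("show", "MethodSpec", function(object) {
  cat(sprintf(
    "MethodSpec: no-ties = %s, ties = %s\n  start = %s, end = %s, ties handled by %s\n",
    object@noTies, object@ties, object@startPolicy, object@endPolicy,
    object@tiePolicy))
})

# Internal: segment table of a path, including the virtual origin segment.
# One row per segment; `size` is the number of entities in the tie group
# that produced the segment's right-hand anchor.
.segments <- function(path) {
  tpB <- path@tp
  fpB <- path@fp
  tpA <- c(0L, utils::head(tpB, -1L))
  fpA <- c(0L, utils::head(fpB, -1L))
  data.frame(tpA = tpA, fpA = fpA, tpB = tpB, fpB = fpB,
             size = (tpB - tpA) + (fpB - fpA))
}

# Internal: connector name and offset for one segment under a spec
.connectorFor <- function(spec, size) {
  if (size > 1L) {
    con <- spec@ties
    if (con == "linear") con <- "line"
    list(connector = con, offset = 1.0)
  } else {
    list(connector = spec@noTies, offset = 0.5)
  }
}

# Internal: area of one segment under a connector.  `precisionA` overrides
# the left-endpoint precision for chord-joined connectors (line, discrete).
.segmentArea <- function(tpA, fpA, tpB, fpB, P, connector, offset,
                         precisionA = NULL) {
  switch(connector,
    line = linearSegmentArea(tpA, fpA, tpB, fpB, P, precisionA),
    step = stepSegmentArea(tpA, fpA, tpB, fpB, P),
    continuous_expectation = continuousSegmentArea(tpA, fpA, tpB, fpB, P),
    discrete_expectation =
      discreteExpectationArea(tpA, fpA, tpB, fpB, P, offset, precisionA),
    stop("unknown connector: ", connector))
}

#' Area under the precision-recall curve
#'
#' Computes AUPRC as the sum of per-segment areas.  Each segment between
#' adjacent anchors is integrated with the connector selected by the tie
#' structure: a segment produced by a multi-entity tie group uses the
#' `ties` connector of the spec, a segment produced by a single entity uses
#' the `noTies` connector.  A virtual origin segment from (tp, fp) = (0, 0)
#' to the first anchor completes the curve down to zero recall; how its left
#' endpoint is treated is governed by the spec's `startPolicy`.
#'
#' @param data a [ScoredLabels-class] object.
#' @param spec a [MethodSpec-class]; default [methodSpec()].
#' @return An [AUPRCResult-class] carrying the value, the spec, and any
#'   issue warnings raised (linear interpolation across ties, forced (0,1)
#'   start, truncated recall range, input-order tie handling, absence of
#'   negatives).
#' @examples
#' d1 <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
#' auprc(d1)                                   # default: 0.904...
#' auprc(d1, methodSpec("step", "step"))       # Average Precision: 11/12
#' @export
auprc <- function(data, spec = methodSpec()) {
  stopifnot(is(data, "ScoredLabels"), is(spec, "MethodSpec"))
  path <- anchorPath(data, tiePolicy = spec@tiePolicy)
  seg <- .segments(path)
  P <- path@P

  warnings <- character(0)
  tiesPresent <- any(.segments(anchorPath(data))$size > 1L)
  if (tiesPresent && spec@ties == "linear" && spec@tiePolicy == "group")
    warnings <- c(warnings,
      "linear interpolation across tied scores; AUPRC may be overly optimistic")
  if (spec@startPolicy == "fixed_0_1")
    warnings <- c(warnings, "curve start forced to (0, 1)")
  if (spec@startPolicy == "first_anchor")
    warnings <- c(warnings, "curve does not reach zero recall")
  if (spec@endPolicy == "truncate_at_last_distinct" && nrow(seg) > 1L)
    warnings <- c(warnings, "curve truncated before full recall")
  if (tiesPresent && spec@tiePolicy == "input_order")
    warnings <- c(warnings,
      "tied scores broken by input order; value depends on row order")
  if (path@N == 0L)
    warnings <- c(warnings, "no negative entities; precision is identically 1")

  if (spec@endPolicy == "truncate_at_last_distinct" && nrow(seg) > 1L)
    seg <- seg[-nrow(seg), , drop = FALSE]

  total <- 0
  for (k in seq_len(nrow(seg))) {
    con <- .connectorFor(spec, seg$size[k])
    precA <- NULL
    if (k == 1L) {
      if (spec@startPolicy == "first_anchor") next
      if (spec@startPolicy == "fixed_0_1") precA <- 1
    }
    total <- total + .segmentArea(seg$tpA[k], seg$fpA[k], seg$tpB[k],
                                  seg$fpB[k], P, con$connector, con$offset,
                                  precA)
  }
  new("AUPRCResult", value = total, spec = spec, warnings = warnings)
}

#' @rdname prcaudit-generics
#' @export
setMethod("auprcValue", "AUPRCResult", function(x) x@value)

#' @rdname prcaudit-generics
#' @export
setMethod("methodOf", "AUPRCResult", function(x) x@spec)

#' @rdname prcaudit-generics
#' @export
setMethod("issueWarnings", "AUPRCResult", function(x) x@warnings)

setMethod("show", "AUPRCResult", function(object) {
  cat(sprintf("AUPRC = %.6f  (no-ties: %s, ties: %s, start: %s, end: %s, ties by %s)\n",
              object@value, object@spec@noTies, object@spec@ties,
              object@spec@startPolicy, object@spec@endPolicy,
              object@spec@tiePolicy))
  for (w in object@warnings) cat("  warning: ", w, "\n", sep = "")
})

#' Average Precision
#'
#' The step-curve AUPRC estimate
#' \eqn{\sum_k (R_k - R_{k-1}) \, P_k}: rectangles at each anchor's
#' precision.  Identical to
#' `auprc(data, methodSpec("step", "step"))`.
#'
#' @inheritParams auprc
#' @return numeric scalar.
#' @examples
#' d1 <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
#' averagePrecision(d1)   # 11/12
#' @export
averagePrecision <- function(data) {
  auprcValue(auprc(data, methodSpec("step", "step")))
}

#' Baseline AUPRC of an uninformative classifier
#'
#' A classifier carrying no information has expected AUPRC equal to the
#' positive-class prevalence P / (P + N); reported values should be judged
#' against this baseline, especially under heavy class imbalance.
#'
#' @param P number of positive entities (>= 1).
#' @param N number of negative entities (>= 0).
#' @return numeric scalar P / (P + N).
#' @examples
#' baselineAuprc(32, 42)        # 0.432...
#' baselineAuprc(4012, 274380)  # 0.0144...
#' @export
baselineAuprc <- function(P, N) {
  if (P < 1) .stopNoPositives()
  stopifnot(N >= 0)
  P / (P + N)
}

#' Area under the ROC curve (trapezoid rule)
#'
#' Builds the ROC from the grouped-tie anchor path and integrates with
#' trapezoids.  This equals the Mann-Whitney pairwise statistic (probability
#' that a random positive outscores a random negative, tied pairs counting
#' one half); [mannWhitneyAuroc()] provides the independent pairwise-count
#' oracle.
#'
#' @inheritParams auprc
#' @return numeric scalar in \[0, 1\].
#' @examples
#' d1 <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
#' auroc(d1)   # 5/6
#' @export
auroc <- function(data) {
  stopifnot(is(data, "ScoredLabels"))
  path <- anchorPath(data)
  if (path@N == 0L)
    .prcStop("prcaudit_no_negatives_error",
             "AUROC undefined: no negative entities")
  seg <- .segments(path)
  # integer numerator keeps the trapezoid sum exact (matches the pairwise count)
  num <- sum((seg$fpB - seg$fpA) * (seg$tpA + seg$tpB))
  num / (2 * path@P * path@N)
}

#' Build an explicit precision-recall curve
#'
#' Returns the full vertex list of the PR curve under a [MethodSpec-class]:
#' the zero-recall start vertex (per `startPolicy`), all anchor points, the
#' interpolated points inserted by the connectors (step corners, discrete
#' expectation vertices, samples of the continuous expectation curve), with
#' the final vertex marked `"end"`.
#'
#' @inheritParams auprc
#' @param nInterp number of chords used to render each continuous-expectation
#'   segment (sampling density; the AUPRC integral itself is closed-form and
#'   unaffected).
#' @return A [PRCurve-class] object.
#' @examples
#' d1 <- scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
#' as.data.frame(prcCurve(d1, methodSpec("line", "linear")))
#' @export
prcCurve <- function(data, spec = methodSpec(), nInterp = 20L) {
  stopifnot(is(data, "ScoredLabels"), is(spec, "MethodSpec"))
  path <- anchorPath(data, tiePolicy = spec@tiePolicy)
  seg <- .segments(path)
  if (spec@endPolicy == "truncate_at_last_distinct" && nrow(seg) > 1L)
    seg <- seg[-nrow(seg), , drop = FALSE]
  P <- path@P

  r <- numeric(0); p <- numeric(0); kind <- character(0)
  addV <- function(rec, prec, k) {
    r <<- c(r, rec); p <<- c(p, prec); kind <<- c(kind, k)
  }

  firstPrec <- seg$tpB[1L] / (seg$tpB[1L] + seg$fpB[1L])
  if (spec@startPolicy == "segment_limit") addV(0, firstPrec, "start")
  if (spec@startPolicy == "fixed_0_1") addV(0, 1, "start")

  for (k in seq_len(nrow(seg))) {
    tpA <- seg$tpA[k]; fpA <- seg$fpA[k]
    tpB <- seg$tpB[k]; fpB <- seg$fpB[k]
    dtp <- tpB - tpA
    con <- .connectorFor(spec, seg$size[k])
    if (dtp > 0) {
      if (con$connector == "step") {
        addV(tpA / P, tpB / (tpB + fpB), "interpolated")
      } else if (con$connector == "discrete_expectation") {
        v <- discreteExpectationVertices(tpA, fpA, tpB, fpB, P, con$offset)
        for (i in seq_len(nrow(v))) addV(v$recall[i], v$precision[i], "interpolated")
      } else if (con$connector == "continuous_expectation") {
        s <- dtp * seq_len(nInterp - 1L) / nInterp
        prec <- expectationPrecision(tpA, fpA, tpB, fpB, s)
        for (i in seq_along(s)) addV((tpA + s[i]) / P, prec[i], "interpolated")
      }
    }
    addV(tpB / P, tpB / (tpB + fpB), "anchor")
  }
  kind[length(kind)] <- "end"

  # drop exact duplicates of consecutive vertices (start vertex can coincide
  # with a step corner at recall 0), keeping the earlier, more specific kind
  keep <- c(TRUE, !(diff(r) == 0 & diff(p) == 0 &
                    kind[-length(kind)] != "anchor"))
  keep[length(keep)] <- TRUE
  new("PRCurve", recall = r[keep], precision = p[keep], kind = kind[keep],
      spec = spec)
}

#' @rdname prcaudit-generics
#' @export
setMethod("recall", "PRCurve", function(x) x@recall)

#' @rdname prcaudit-generics
#' @export
setMethod("precision", "PRCurve", function(x) x@precision)

#' @describeIn prcCurve number of curve vertices.
#' @param x a `PRCurve` object.
#' @export
setMethod("length", "PRCurve", function(x) length(x@recall))

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d vertices (%d anchors), recall %.3f to %.3f\n",
              length(object@recall), sum(object@kind %in% c("anchor", "end")),
              min(object@recall), max(object@recall)))
})

#' Coerce a PRCurve to a data.frame
#'
#' @param x a [PRCurve-class] object.
#' @param ... unused.
#' @return data.frame with columns recall, precision, kind.
#' @exportS3Method base::as.data.frame
#' @export as.data.frame.PRCurve
as.data.frame.PRCurve <- function(x, ...) {
  data.frame(recall = x@recall, precision = x@precision, kind = x@kind)
}
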