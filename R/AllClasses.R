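#' @import methods
NULL

#' ScoredLabels: paired classification scores and binary labels
#'
#' Container for the output of one binary classifier on one data set: a real
#' score per entity (larger = more confidently positive) and the true class
#' label (1 = positive, 0 = negative).  Scores may contain ties; row order is
#' preserved because some emulated tools are sensitive to it.
#'
#' @slot scores numeric vector of finite classification scores.
#' @slot labels integer vector of 0/1 class labels, same length as `scores`.
#'
#' @seealso [scoredLabels()] for the validating constructor, [groupTies()],
#'   [anchorPath()], [auprc()].
#' @exportClass ScoredLabels
setClass("ScoredLabels",
         representation(scores = "numeric", labels = "integer"))

setValidity("ScoredLabels", function(object) {
  if (length(object@scores) == 0L) return("empty input")
  if (length(object@scores) != length(object@labels))
    return("scores and labels have different lengths")
  if (any(!is.finite(object@scores))) return("non-finite score")
  if (!all(object@labels %in% c(0L, 1L))) return("non-binary label")
  TRUE
})

#' AnchorPath: cumulative (tp, fp) counts at each score threshold
#'
#' The ordered sequence of anchor points of a precision-recall (or ROC) curve.
#' Point k corresponds to thresholding at the k-th largest distinct score and
#' stores the cumulative true-positive and false-positive counts; the final
#' point is always (P, N).
#'
#' @slot threshold numeric, strictly decreasing score thresholds (one per
#'   anchor; under the input-order tie policy one per entity, so values may
#'   repeat).
#' @slot tp integer, cumulative true positives at each threshold.
#' @slot fp integer, cumulative false positives at each threshold.
#' @slot P integer, total number of positive entities.
#' @slot N integer, total number of negative entities.
#'
#' @seealso [anchorPath()], [recall()], [precision()]
#' @exportClass AnchorPath
setClass("AnchorPath",
         representation(threshold = "numeric", tp = "integer",
                        fp = "integer", P = "integer", N = "integer"))

setValidity("AnchorPath", function(object) {
  n <- length(object@tp)
  if (n == 0L) return("anchor path has no points")
  if (length(object@fp) != n || length(object@threshold) != n)
    return("tp, fp and threshold must have equal lengths")
  if (any(object@tp < 0L) || any(object@fp < 0L))
    return("negative cumulative counts")
  if (is.unsorted(object@tp) || is.unsorted(object@fp))
    return("cumulative counts must be non-decreasing")
  if (object@tp[n] != object@P || object@fp[n] != object@N)
    return("final anchor must equal (P, N)")
  TRUE
})

.NO_TIES_CONNECTORS <- c("line", "discrete_expectation",
                         "continuous_expectation", "step")
.TIES_CONNECTORS <- c("linear", "discrete_expectation",
                      "continuous_expectation", "step")
.START_POLICIES <- c("segment_limit", "fixed_0_1", "first_anchor")
.END_POLICIES <- c("full_recall", "truncate_at_last_distinct")
.TIE_POLICIES <- c("group", "input_order")

#' MethodSpec: a complete recipe for computing one AUPRC value
#'
#' Bundles the five choices that together determine a PR curve and its area:
#' the connector used between anchors separated by a single entity, the
#' connector used across a multi-entity tie block, the policy for the
#' zero-recall start point, the policy for the end of the recall range, and
#' whether tied scores are grouped into one anchor or broken by input order.
#'
#' @slot noTies one of `"line"`, `"discrete_expectation"`,
#'   `"continuous_expectation"`, `"step"`.
#' @slot ties one of `"linear"`, `"discrete_expectation"`,
#'   `"continuous_expectation"`, `"step"`.
#' @slot startPolicy one of `"segment_limit"`, `"fixed_0_1"`, `"first_anchor"`.
#' @slot endPolicy one of `"full_recall"`, `"truncate_at_last_distinct"`.
#' @slot tiePolicy one of `"group"`, `"input_order"`.
#'
#' @seealso [methodSpec()], [auprc()], [toolProfile()]
#' @exportClass MethodSpec
setClass("MethodSpec",
         representation(noTies = "character", ties = "character",
                        startPolicy = "character", endPolicy = "character",
                        tiePolicy = "character"))

setValidity("MethodSpec", function(object) {
  if (!object@noTies %in% .NO_TIES_CONNECTORS)
    return(sprintf("unknown no-ties connector '%s'", object@noTies))
  if (!object@ties %in% .TIES_CONNECTORS)
    return(sprintf("unknown ties connector '%s'", object@ties))
  if (!object@startPolicy %in% .START_POLICIES)
    return(sprintf("unknown start policy '%s'", object@startPolicy))
  if (!object@endPolicy %in% .END_POLICIES)
    return(sprintf("unknown end policy '%s'", object@endPolicy))
  if (!object@tiePolicy %in% .TIE_POLICIES)
    return(sprintf("unknown tie policy '%s'", object@tiePolicy))
  TRUE
})

#' PRCurve: an explicit precision-recall curve
#'
#' The vertex list of a PR curve built under a [MethodSpec-class]: anchor
#' points, interpolated points inserted by the chosen connectors, and the
#' zero-recall start vertex.  Straight lines between consecutive vertices
#' reproduce the curve exactly for the line, step and discrete-expectation
#' connectors; for the continuous-expectation connector the interior vertices
#' are samples of the closed-form curve.
#'
#' @slot recall numeric vertex recalls, non-decreasing.
#' @slot precision numeric vertex precisions in \[0, 1\].
#' @slot kind character, one of `"start"`, `"anchor"`, `"interpolated"`,
#'   `"end"` per vertex.
#' @slot spec the [MethodSpec-class] used to build the curve.
#'
#' @seealso [prcCurve()], [writeCurve()]
#' @exportClass PRCurve
setClass("PRCurve",
         representation(recall = "numeric", precision = "numeric",
                        kind = "character", spec = "MethodSpec"))

setValidity("PRCurve", function(object) {
  n <- length(object@recall)
  if (length(object@precision) != n || length(object@kind) != n)
    return("recall, precision and kind must have equal lengths")
  if (is.unsorted(object@recall)) return("recall must be non-decreasing")
  if (!all(object@kind %in% c("start", "anchor", "interpolated", "end")))
    return("invalid vertex kind")
  TRUE
})

#' AUPRCResult: an AUPRC value together with how it was computed
#'
#' @slot value numeric scalar, the area.
#' @slot spec the [MethodSpec-class] used.
#' @slot warnings character vector of issue flags raised during computation
#'   (e.g. linear interpolation across ties, forced (0,1) start, truncated
#'   recall range, input-order tie handling).
#'
#' @seealso [auprc()]
#' @exportClass AUPRCResult
setClass("AUPRCResult",
         representation(value = "numeric", spec = "MethodSpec",
                        warnings = "character"))

#' ToolProfile: a named preset emulating one evaluation tool's method choices
#'
#' @slot name character identifier of the emulated tool/method row.
#' @slot spec the [MethodSpec-class] the tool's choices correspond to.
#' @slot issues integer vector, subset of 1:5, the conceptual issues the
#'   combination is susceptible to (1 linear tie interpolation, 2 forced
#'   (0,1) start, 3 incomplete recall range, 4 input-order tie handling,
#'   5 omitted anchor points).
#'
#' @seealso [toolProfile()], [listToolProfiles()]
#' @exportClass ToolProfile
setClass("ToolProfile",
         representation(name = "character", spec = "MethodSpec",
                        issues = "integer"))

#' ComparisonTable: AUPRC values per classifier and per method profile
#'
#' Result of [compareMethods()] (one classifier, many profiles) or
#' [rankClassifiers()] (many classifiers, many profiles).  Rows are
#' classifiers, columns are profiles.
#'
#' @slot values numeric matrix of AUPRC values (classifiers x profiles).
#' @slot digits integer, rounding used when counting distinct values.
#'
#' @seealso [distinctValues()], [valueSpread()], [rankMatrix()],
#'   [profileCorrelations()]
#' @exportClass ComparisonTable
setClass("ComparisonTable",
         representation(values = "matrix", digits = "integer"))

#' AuditReport: susceptibility of one data set to AUPRC computation issues
#'
#' @slot tieFraction numeric, share of entities that sit in a multi-entity
#'   tie group.
#' @slot inflation numeric, AUPRC(linear ties, forced (0,1) start) minus
#'   AUPRC(continuous expectation ties, segment-limit start).
#' @slot startEffect numeric, change in AUPRC caused by forcing the (0,1)
#'   start alone (all other choices at the package default).
#' @slot orderSensitivity numeric, max minus min AUPRC over random input-row
#'   shuffles under the input-order tie policy.
#' @slot nShuffles integer, number of shuffles used for `orderSensitivity`.
#' @slot values named numeric, the underlying AUPRC values.
#'
#' @seealso [auditScores()]
#' @exportClass AuditReport
setClass("AuditReport",
         representation(tieFraction = "numeric", inflation = "numeric",
                        startEffect = "numeric", orderSensitivity = "numeric",
                        nShuffles = "integer", values = "numeric"))
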