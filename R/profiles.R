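# The emulated tool/method combinations: connector pair, curve policies and
# the conceptual issues each combination is susceptible to.
# Issue codes: 1 linear interpolation across ties, 2 forced (0,1) start,
# 3 incomplete recall range, 4 input-order tie handling, 5 omitted anchors.
.PROFILE_TABLE <- list(
  "ROCR"             = list("line", "discrete_expectation", "fixed_0_1",
                            "full_recall", "group", c(2L, 5L)),
  "Weka"             = list("step", "step", "segment_limit",
                            "full_recall", "group", integer(0)),
  "scikit-learn-PR"  = list("line", "linear", "fixed_0_1",
                            "full_recall", "group", c(1L, 2L)),
  "scikit-learn-AP"  = list("step", "step", "segment_limit",
                            "full_recall", "group", integer(0)),
  "PerfMeas"         = list("line", "linear", "segment_limit",
                            "truncate_at_last_distinct", "input_order",
                            c(3L, 4L)),
  "PRROC-discrete"   = list("line", "discrete_expectation", "segment_limit",
                            "full_recall", "group", integer(0)),
  "PRROC-continuous" = list("continuous_expectation", "continuous_expectation",
                            "segment_limit", "full_recall", "group", integer(0)),
  "TensorFlow"       = list("continuous_expectation", "continuous_expectation",
                            "segment_limit", "full_recall", "group", integer(0)),
  "precrec"          = list("discrete_expectation", "discrete_expectation",
                            "segment_limit", "full_recall", "group", integer(0)),
  "TorchEval"        = list("step", "step", "segment_limit",
                            "full_recall", "group", integer(0)),
  "MLeval"           = list("line", "linear", "first_anchor",
                            "full_recall", "group", c(1L, 3L)),
  "yardstick-PR"     = list("line", "linear", "fixed_0_1",
                            "full_recall", "group", c(1L, 2L)),
  "yardstick-AP"     = list("step", "step", "segment_limit",
                            "full_recall", "group", integer(0))
)

.PROFILE_ALIASES <- c("sklearn-pr" = "scikit-learn-PR",
                      "sklearn-ap" = "scikit-learn-AP",
                      "weka-ap" = "Weka",
                      "torcheval-ap" = "TorchEval")

#' Named presets emulating popular tools' AUPRC method combinations
#'
#' `toolProfile()` returns the [MethodSpec-class] preset (plus issue flags)
#' corresponding to one row of the tool-behaviour catalogue: the connector a
#' tool uses between untied anchors, the connector it uses across tie
#' blocks, and its curve start/end and tie-ordering behaviour.  Tools
#' offering several methods appear as several rows (e.g. the PR-trapezoid
#' and AP variants of scikit-learn and yardstick; the discrete and
#' continuous expectation variants of PRROC).  Tool-specific programming
#' bugs are not emulated — only the documented method combinations.
#'
#' @param name a profile name from `listToolProfiles()` (case-insensitive;
#'   a few short aliases such as `"sklearn-ap"` are accepted).
#' @return `toolProfile()`: a [ToolProfile-class]; `listToolProfiles()`: a
#'   character vector of the available profile names.
#' @examples
#' toolProfile("precrec")
#' listToolProfiles()
#' @export
toolProfile <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- name
  low <- tolower(key)
  if (low %in% names(.PROFILE_ALIASES)) key <- .PROFILE_ALIASES[[low]]
  hit <- match(tolower(key), tolower(names(.PROFILE_TABLE)))
  if (is.na(hit))
    .prcStop("prcaudit_profile_error",
             sprintf("unknown profile '%s'; see listToolProfiles()", name))
  key <- names(.PROFILE_TABLE)[hit]
  row <- .PROFILE_TABLE[[key]]
  new("ToolProfile", name = key,
      spec = methodSpec(row[[1]], row[[2]], row[[3]], row[[4]], row[[5]]),
      issues = row[[6]])
}

#' @rdname toolProfile
#' @export
listToolProfiles <- function() names(.PROFILE_TABLE)

#' @rdname prcaudit-generics
#' @export
setMethod("profileName", "ToolProfile", function(x) x@name)

#' @rdname prcaudit-generics
#' @export
setMethod("methodOf", "ToolProfile", function(x) x@spec)

#' @rdname prcaudit-generics
#' @export
setMethod("issueFlags", "ToolProfile", function(x) x@issues)

setMethod("show", "ToolProfile", function(object) {
  flags <- if (length(object@issues)) paste(object@issues, collapse = ",")
           else "none"
  cat(sprintf("ToolProfile '%s' (issues: %s)\n", object@name, flags))
  show(object@spec)
})

# Internal: normalise a profiles argument into a named list of ToolProfile
.resolveProfiles <- function(profiles) {
  if (identical(profiles, "all")) profiles <- listToolProfiles()
  if (is.character(profiles)) profiles <- lapply(profiles, toolProfile)
  if (is(profiles, "ToolProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "ToolProfile")))
  names(profiles) <- vapply(profiles, profileName, character(1))
  profiles
}

#' Compare AUPRC values across method profiles
#'
#' Computes the AUPRC of one classifier under each requested profile, so the
#' discrepancies produced by different tools' method choices can be seen on
#' one data set.
#'
#' @param data a [ScoredLabels-class] object.
#' @param profiles `"all"`, a character vector of profile names, or a list
#'   of [ToolProfile-class] objects.
#' @param digits rounding used when counting distinct values (default 3).
#' @return A [ComparisonTable-class] (one row).
#' @examples
#' const <- scoredLabels(rep(0.5, 5), c(1, 1, 1, 0, 0))
#' ct <- compareMethods(const, c("scikit-learn-AP", "PRROC-continuous",
#'                               "scikit-learn-PR"))
#' comparisonValues(ct)
#' distinctValues(ct)
#' valueSpread(ct)
#' @export
compareMethods <- function(data, profiles = "all", digits = 3L) {
  profiles <- .resolveProfiles(profiles)
  vals <- vapply(profiles,
                 function(p) auprcValue(auprc(data, methodOf(p))),
                 numeric(1))
  m <- matrix(vals, nrow = 1L,
              dimnames = list("classifier", names(profiles)))
  new("ComparisonTable", values = m, digits = as.integer(digits))
}

#' Rank several classifiers under several method profiles
#'
#' Computes an AUPRC matrix (classifiers x profiles), per-profile ranks
#' (rank 1 = largest AUPRC, tied values receive averaged ranks), and the
#' pairwise Pearson correlation between the profiles' AUPRC vectors —
#' the rank-discordance analysis that exposes tools ranking the same
#' classifiers differently.
#'
#' @param datasets a named list of two or more [ScoredLabels-class] objects,
#'   one per classifier.
#' @inheritParams compareMethods
#' @return A [ComparisonTable-class].
#' @examples
#' tieHeavy <- tieBlockFixture(list(c(3, 2)))
#' tieFree  <- tieBlockFixture(list(c(1,0), c(0,1), c(1,0), c(0,1), c(1,0)))
#' ct <- rankClassifiers(list(X = tieHeavy, Y = tieFree),
#'                       c("scikit-learn-PR", "Weka"))
#' rankMatrix(ct)
#' @export
rankClassifiers <- function(datasets, profiles = "all", digits = 3L) {
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("classifier", seq_along(datasets))
  profiles <- .resolveProfiles(profiles)
  m <- vapply(profiles,
              function(p) vapply(datasets,
                                 function(d) auprcValue(auprc(d, methodOf(p))),
                                 numeric(1)),
              numeric(length(datasets)))
  m <- matrix(m, nrow = length(datasets),
              dimnames = list(names(datasets), names(profiles)))
  new("ComparisonTable", values = m, digits = as.integer(digits))
}

#' @rdname prcaudit-generics
#' @export
setMethod("comparisonValues", "ComparisonTable", function(x) x@values)

#' @rdname prcaudit-generics
#' @export
setMethod("distinctValues", "ComparisonTable", function(x, digits = x@digits) {
  apply(round(x@values, digits), 1L, function(v) length(unique(v)))
})

#' @rdname prcaudit-generics
#' @export
setMethod("valueSpread", "ComparisonTable", function(x) {
  apply(x@values, 1L, function(v) max(v) - min(v))
})

#' @rdname prcaudit-generics
#' @export
setMethod("rankMatrix", "ComparisonTable", function(x) {
  apply(x@values, 2L, function(v) rank(-v, ties.method = "average"))
})

#' @rdname prcaudit-generics
#' @export
setMethod("profileCorrelations", "ComparisonTable", function(x) {
  stats::cor(x@values)
})

setMethod("show", "ComparisonTable", function(object) {
  cat(sprintf("ComparisonTable: %d classifier(s) x %d profile(s)\n",
              nrow(object@values), ncol(object@values)))
  print(round(object@values, object@digits))
  cat("distinct values (", object@digits, " dp): ",
      paste(distinctValues(object), collapse = ", "),
      "; spread: ", paste(signif(valueSpread(object), 3), collapse = ", "),
      "\n", sep = "")
})

#' Audit a data set for AUPRC computation issues
#'
#' Quantifies how susceptible a score/label set is to the known AUPRC
#' computation issues:
#' \describe{
#'   \item{tie fraction}{share of entities in multi-entity tie groups — the
#'     raw material for all tie-handling discrepancies.}
#'   \item{inflation}{AUPRC under linear tie interpolation with a forced
#'     (0,1) start minus AUPRC under the issue-free default (continuous
#'     expectation ties, segment-limit start): the headline
#'     "overly-optimistic" effect.}
#'   \item{start effect}{change caused by the forced (0,1) start alone, all
#'     other choices at the default.}
#'   \item{order sensitivity}{max minus min AUPRC over seeded random input
#'     row shuffles under the input-order tie policy; nonzero only when ties
#'     are present.}
#' }
#'
#' @param data a [ScoredLabels-class] object.
#' @param nShuffles number of random row shuffles (default 100).
#' @param seed integer seed for the shuffles.
#' @return An [AuditReport-class].
#' @examples
#' const <- scoredLabels(rep(0.5, 5), c(1, 1, 1, 0, 0))
#' auditScores(const, nShuffles = 20, seed = 1)
#' @export
auditScores <- function(data, nShuffles = 100L, seed = 1L) {
  stopifnot(is(data, "ScoredLabels"))
  g <- groupTies(data)
  sizes <- g$n_pos + g$n_neg
  tieFraction <- sum(sizes[sizes > 1L]) / length(data)

  ref <- auprcValue(auprc(data, methodSpec()))
  linFixed <- auprcValue(auprc(data, methodSpec("line", "linear", "fixed_0_1")))
  fixedOnly <- auprcValue(auprc(data, methodSpec(startPolicy = "fixed_0_1")))

  orderSpec <- methodSpec("line", "linear", tiePolicy = "input_order")
  if (tieFraction == 0) {
    vals <- auprcValue(auprc(data, orderSpec))
    nShuffles <- 0L
  } else {
    vals <- .withSeed(seed, {
      vapply(seq_len(nShuffles), function(i) {
        o <- sample.int(length(data))
        shuffled <- scoredLabels(scores(data)[o], labels(data)[o])
        auprcValue(auprc(shuffled, orderSpec))
      }, numeric(1))
    })
    vals <- c(auprcValue(auprc(data, orderSpec)), vals)
  }

  new("AuditReport",
      tieFraction = tieFraction,
      inflation = linFixed - ref,
      startEffect = fixedOnly - ref,
      orderSensitivity = max(vals) - min(vals),
      nShuffles = as.integer(nShuffles),
      values = c(reference = ref, linear_fixed_start = linFixed,
                 fixed_start_only = fixedOnly,
                 input_order_min = min(vals), input_order_max = max(vals)))
}

#' @describeIn auditScores the report as a plain named list (used for the
#'   JSON export of the command-line `audit` subcommand).
#' @param report an [AuditReport-class].
#' @export
auditAsList <- function(report) {
  stopifnot(is(report, "AuditReport"))
  list(tie_fraction = report@tieFraction,
       inflation = report@inflation,
       start_effect = report@startEffect,
       order_sensitivity = report@orderSensitivity,
       n_shuffles = report@nShuffles,
       values = as.list(report@values))
}

setMethod("show", "AuditReport", function(object) {
  cat("AUPRC issue audit\n")
  cat(sprintf("  tie fraction:          %.3f\n", object@tieFraction))
  cat(sprintf("  inflation (lin+fixed): %+.4f\n", object@inflation))
  cat(sprintf("  start-point effect:    %+.4f\n", object@startEffect))
  cat(sprintf("  order sensitivity:     %.4f (%d shuffles)\n",
              object@orderSensitivity, object@nShuffles))
})
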