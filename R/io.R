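#' Read scores and labels from delimited text
#'
#' Reads one classifier's scores and labels from a TSV/CSV file, one row per
#' entity.  Row order is preserved (it matters under the input-order tie
#' policy).  Labels must be literal 0/1; "truthy" strings are rejected so
#' that label-polarity mistakes fail loudly instead of silently flipping the
#' positive class.
#'
#' @param path file path.  Lines starting with `#` are skipped.
#' @param scoreCol,labelCol column name (with header) or 1-based column
#'   index.  Defaults `"score"` and `"label"`.
#' @param delim field delimiter; `"\t"` (default) or `","` etc.
#' @param header whether the first non-comment line is a header row.
#' @return A validated [ScoredLabels-class].
#' @seealso [writeScoredLabels()]
#' @export
readScoredLabels <- function(path, scoreCol = "score", labelCol = "label",
                             delim = "\t", header = TRUE) {
  if (!file.exists(path))
    .prcStop("prcaudit_io_error", sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = delim, header = header,
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .stopEmpty()
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(df))
        .prcStop("prcaudit_io_error",
                 sprintf("%s column index %d out of range", what, col))
      df[[col]]
    } else {
      if (!col %in% names(df))
        .prcStop("prcaudit_io_error",
                 sprintf("missing column '%s' in %s", col, path))
      df[[col]]
    }
  }
  rawScore <- pick(scoreCol, "score")
  rawLabel <- pick(labelCol, "label")
  sc <- suppressWarnings(as.numeric(rawScore))
  if (anyNA(sc)) {
    bad <- which(is.na(sc))[1L]
    .prcStop("prcaudit_io_error",
             sprintf("unparseable score '%s' at data row %d", rawScore[bad], bad))
  }
  if (!all(rawLabel %in% c("0", "1"))) {
    bad <- which(!rawLabel %in% c("0", "1"))[1L]
    .prcStop("prcaudit_io_error",
             sprintf("label must be 0 or 1; found '%s' at data row %d",
                     rawLabel[bad], bad))
  }
  scoredLabels(sc, as.integer(rawLabel))
}

#' Write scores and labels as delimited text
#'
#' @param x a [ScoredLabels-class] object.
#' @param path output file path.
#' @param delim field delimiter (default tab).
#' @param comment optional character vector written as leading `#` comment
#'   lines (e.g. a record of the generating configuration).
#' @return `path`, invisibly.
#' @export
writeScoredLabels <- function(x, path, delim = "\t", comment = NULL) {
  stopifnot(is(x, "ScoredLabels"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste("score", "label", sep = delim), con)
  writeLines(paste(format(scores(x), digits = 17, trim = TRUE, scientific = FALSE),
                   labels(x), sep = delim), con)
  invisible(path)
}

#' Export a PR curve as TSV
#'
#' Writes the vertex list (columns `recall`, `precision`, `kind`) of a
#' [PRCurve-class] to a tab-separated file.
#'
#' @param curve a [PRCurve-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "PRCurve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize an AUPRCResult as JSON
#'
#' @param result an [AUPRCResult-class] object.
#' @return A JSON string with fields `value` (full double precision),
#'   `method` and `warnings`.
#' @export
resultToJSON <- function(result) {
  stopifnot(is(result, "AUPRCResult"))
  spec <- methodOf(result)
  jsonlite::toJSON(list(
    value = auprcValue(result),
    method = list(no_ties = spec@noTies, ties = spec@ties,
                  start_policy = spec@startPolicy, end_policy = spec@endPolicy,
                  tie_policy = spec@tiePolicy),
    warnings = issueWarnings(result)
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
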