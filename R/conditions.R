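# Classed errors so callers can distinguish failure modes programmatically.
# All conditions also inherit from "prcaudit_error".
.prcStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "prcaudit_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}

.stopLengthMismatch <- function()
  .prcStop("prcaudit_length_error", "length mismatch: scores and labels differ in length")
.stopNonBinary <- function()
  .prcStop("prcaudit_label_error", "non-binary label: labels must be 0 or 1")
.stopNonFinite <- function()
  .prcStop("prcaudit_score_error", "non-finite score: scores must be finite numbers")
.stopEmpty <- function()
  .prcStop("prcaudit_empty_error", "empty input: at least one entity is required")
.stopNoPositives <- function()
  .prcStop("prcaudit_no_positives_error", "AUPRC undefined: no positive entities")
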