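#' @name prcaudit-generics
#' @title Accessor generics
#' @description Accessor generics for the S4 classes in this package.
#' @param x an object.
#' @param ... further arguments for methods.
#' @keywords internal
NULL

#' @rdname prcaudit-generics
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname prcaudit-generics
#' @param object an object (for the `labels` generic, promoted from base R).
#' @export
setGeneric("labels", function(object, ...) standardGeneric("labels"))

#' @rdname prcaudit-generics
#' @export
setGeneric("nPos", function(x) standardGeneric("nPos"))

#' @rdname prcaudit-generics
#' @export
setGeneric("nNeg", function(x) standardGeneric("nNeg"))

#' @rdname prcaudit-generics
#' @export
setGeneric("recall", function(x) standardGeneric("recall"))

#' @rdname prcaudit-generics
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))

#' @rdname prcaudit-generics
#' @export
setGeneric("auprcValue", function(x) standardGeneric("auprcValue"))

#' @rdname prcaudit-generics
#' @export
setGeneric("methodOf", function(x) standardGeneric("methodOf"))

#' @rdname prcaudit-generics
#' @export
setGeneric("issueWarnings", function(x) standardGeneric("issueWarnings"))

#' @rdname prcaudit-generics
#' @export
setGeneric("profileName", function(x) standardGeneric("profileName"))

#' @rdname prcaudit-generics
#' @export
setGeneric("issueFlags", function(x) standardGeneric("issueFlags"))

#' @rdname prcaudit-generics
#' @export
setGeneric("comparisonValues", function(x) standardGeneric("comparisonValues"))

#' @rdname prcaudit-generics
#' @export
setGeneric("distinctValues", function(x, ...) standardGeneric("distinctValues"))

#' @rdname prcaudit-generics
#' @export
setGeneric("valueSpread", function(x) standardGeneric("valueSpread"))

#' @rdname prcaudit-generics
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))

#' @rdname prcaudit-generics
#' @export
setGeneric("profileCorrelations", function(x) standardGeneric("profileCorrelations"))
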