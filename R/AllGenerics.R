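#' @name ihcquant-accessors
#' @title Accessors for ihcquant classes
#'
#' @description Slot access for the package's S4 classes goes through these
#' accessors; slots are not part of the supported interface.
#'
#' @param x an ihcquant S4 object (see individual methods).
#' @param d numeric threshold(s), for [probabilityAtLeast()].
NULL

#' @rdname ihcquant-accessors
#' @export
setGeneric("rangeLo", function(x) standardGeneric("rangeLo"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("rangeHi", function(x) standardGeneric("rangeHi"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("objectMask", function(x) standardGeneric("objectMask"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("objectFeatures", function(x) standardGeneric("objectFeatures"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("objectPixels", function(x) standardGeneric("objectPixels"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("stepTag", function(x) standardGeneric("stepTag"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("macroUsed", function(x) standardGeneric("macroUsed"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("selectedObjects", function(x) standardGeneric("selectedObjects"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("stepMaps", function(x) standardGeneric("stepMaps"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("backgroundAssessment",
           function(x) standardGeneric("backgroundAssessment"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("backgroundClass", function(x) standardGeneric("backgroundClass"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("backgroundAreas", function(x) standardGeneric("backgroundAreas"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("backgroundRatio", function(x) standardGeneric("backgroundRatio"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("estimatedNuclei", function(x) standardGeneric("estimatedNuclei"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("imageComplexity", function(x) standardGeneric("imageComplexity"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("sceneNuclei", function(x) standardGeneric("sceneNuclei"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("backgroundLevel", function(x) standardGeneric("backgroundLevel"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("backgroundPixels", function(x) standardGeneric("backgroundPixels"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("meanDifference", function(x) standardGeneric("meanDifference"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("limitsOfAgreement",
           function(x) standardGeneric("limitsOfAgreement"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("agreementPoints", function(x) standardGeneric("agreementPoints"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))
#' @rdname ihcquant-accessors
#' @export
setGeneric("probabilityAtLeast",
           function(x, d) standardGeneric("probabilityAtLeast"))
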