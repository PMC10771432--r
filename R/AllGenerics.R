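#' @include AllClasses.R
NULL

#' Accessors for cordflow classes
#'
#' Small accessor generics for the S4 containers: frame data, calibration,
#' flow values, validity masks, profile bins and zone parameters.
#'
#' @param object a cordflow S4 object.
#' @return The corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))
#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("flowValues", function(object) standardGeneric("flowValues"))
#' @rdname accessors
#' @export
setGeneric("flowUnits", function(object) standardGeneric("flowUnits"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("indexValues", function(object) standardGeneric("indexValues"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setGeneric("trueFlow", function(object) standardGeneric("trueFlow"))
#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))
#' @rdname accessors
#' @export
setGeneric("injuryGeometry", function(object) standardGeneric("injuryGeometry"))
#' @rdname accessors
#' @export
setGeneric("labelingOk", function(object) standardGeneric("labelingOk"))
#' @rdname accessors
#' @export
setGeneric("injuryExtent", function(object) standardGeneric("injuryExtent"))
#' @rdname accessors
#' @export
setGeneric("decayConstant", function(object) standardGeneric("decayConstant"))
#' @rdname accessors
#' @export
setGeneric("fitOk", function(object) standardGeneric("fitOk"))
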