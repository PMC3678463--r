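#' Accessors
#'
#' Small accessor generics for the package's S4 classes: `pixels()` returns
#' the gray-level matrix, `pitchMm()` the pixel pitch in mm, `siteLabel()`
#' the femoral site, `profileValues()` the depth-ordered intensity vector,
#' `levelValues()` the five depth-level means, `overallMean()` the mean of
#' all 25 samples, and `intensitySlope()` the least-squares slope over the
#' first two levels.
#'
#' @param object an object of the corresponding class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pitchMm", function(object) standardGeneric("pitchMm"))
#' @rdname accessors
#' @export
setGeneric("siteLabel", function(object) standardGeneric("siteLabel"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("levelValues", function(object) standardGeneric("levelValues"))
#' @rdname accessors
#' @export
setGeneric("overallMean", function(object) standardGeneric("overallMean"))
#' @rdname accessors
#' @export
setGeneric("intensitySlope", function(object) standardGeneric("intensitySlope"))

#' @rdname accessors
setMethod("pixels", "BModeImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixels", "ROISegment", function(object) object@pixels)
#' @rdname accessors
setMethod("pitchMm", "BModeImage", function(object) object@pitchMm)
#' @rdname accessors
setMethod("pitchMm", "ROISegment", function(object) object@pitchMm)
#' @rdname accessors
setMethod("pitchMm", "BoneProfile", function(object) object@pitchMm)
#' @rdname accessors
setMethod("siteLabel", "BModeImage", function(object) object@site)
#' @rdname accessors
setMethod("siteLabel", "DepthLevelSummary", function(object) object@site)
#' @rdname accessors
setMethod("profileValues", "BoneProfile", function(object) object@values)
#' @rdname accessors
setMethod("levelValues", "DepthLevelSummary", function(object) object@levelMeans)
#' @rdname accessors
setMethod("overallMean", "DepthLevelSummary", function(object) object@levelAll)
#' @rdname accessors
setMethod("intensitySlope", "DepthLevelSummary", function(object) object@slope)
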