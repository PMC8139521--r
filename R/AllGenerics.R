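#' @name sptEM-accessors
#' @title Accessors for sptEM classes
#' @description Slot accessors for the central S4 classes. Use these rather
#'   than `@` access.
#' @param object an sptEM S4 object
NULL

#' @rdname sptEM-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname sptEM-accessors
#' @export
setGeneric("sceneConfigOf", function(object) standardGeneric("sceneConfigOf"))

#' @rdname sptEM-accessors
#' @export
setGeneric("truePositions", function(object) standardGeneric("truePositions"))

#' @rdname sptEM-accessors
#' @export
setGeneric("framePositions", function(object) standardGeneric("framePositions"))

#' @rdname sptEM-accessors
#' @export
setGeneric("subPositions", function(object) standardGeneric("subPositions"))

#' @rdname sptEM-accessors
#' @export
setGeneric("readoutVariance", function(object) standardGeneric("readoutVariance"))

#' @rdname sptEM-accessors
#' @export
setGeneric("gainMap", function(object) standardGeneric("gainMap"))

#' @rdname sptEM-accessors
#' @export
setGeneric("smoothedMean", function(object) standardGeneric("smoothedMean"))

#' @rdname sptEM-accessors
#' @export
setGeneric("smoothedCov", function(object) standardGeneric("smoothedCov"))

#' @rdname sptEM-accessors
#' @export
setGeneric("lagOneCov", function(object) standardGeneric("lagOneCov"))

#' @rdname sptEM-accessors
#' @export
setGeneric("initialState", function(object) standardGeneric("initialState"))

#' @rdname sptEM-accessors
#' @export
setGeneric("thetaTrace", function(object) standardGeneric("thetaTrace"))

#' @rdname sptEM-accessors
#' @export
setGeneric("finalTheta", function(object) standardGeneric("finalTheta"))

#' @rdname sptEM-accessors
#' @export
setGeneric("posteriorOf", function(object) standardGeneric("posteriorOf"))

#' @rdname sptEM-accessors
#' @export
setGeneric("emFailed", function(object) standardGeneric("emFailed"))

#' @rdname sptEM-accessors
#' @export
setGeneric("windowOrigins", function(object) standardGeneric("windowOrigins"))
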