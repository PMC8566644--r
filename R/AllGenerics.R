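#' @include utils.R
NULL

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' @export
setGeneric("frameEnds", function(x) standardGeneric("frameEnds"))

#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' @export
setGeneric("frameMids", function(x) standardGeneric("frameMids"))

#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @export
setGeneric("studyVolume", function(x) standardGeneric("studyVolume"))

#' @export
setGeneric("studySchedule", function(x) standardGeneric("studySchedule"))

#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @export
setGeneric("imageKind", function(x) standardGeneric("imageKind"))

#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))

#' @export
setGeneric("classWeights", function(x) standardGeneric("classWeights"))

#' @export
setGeneric("metricTable", function(x) standardGeneric("metricTable"))
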