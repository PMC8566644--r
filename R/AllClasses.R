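#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# FrameSchedule
# ---------------------------------------------------------------------------

#' Dynamic acquisition frame schedule
#'
#' An ordered set of contiguous, non-overlapping time frames (in seconds post
#' injection) describing how a dynamic PET acquisition was binned.
#'
#' @slot start numeric vector of frame start times (seconds); first must be 0.
#' @slot end numeric vector of frame end times (seconds).
#'
#' @seealso [frameSchedule()], [defaultFrameSchedule()]
#' @export
setClass("FrameSchedule", representation(start = "numeric", end = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; e <- object@end
  if (length(s) != length(e)) return("start and end must have equal length")
  if (!length(s)) return("schedule must contain at least one frame")
  if (s[1L] != 0) return("first frame must start at 0 s")
  if (any(e <= s)) return("every frame must have positive duration")
  if (length(s) > 1L && any(abs(s[-1L] - e[-length(e)]) > 1e-9))
    return("frames must be contiguous: frame k+1 must start where frame k ends")
  TRUE
})

#' Construct a frame schedule from frame durations
#'
#' @param durations numeric vector of frame durations in seconds.
#' @return A [FrameSchedule-class] object starting at 0 s.
#' @examples
#' frameSchedule(c(rep(10, 7), rep(30, 3), 120, rep(300, 3), rep(600, 2)))
#' @export
frameSchedule <- function(durations) {
  e <- cumsum(as.numeric(durations))
  new("FrameSchedule", start = c(0, head(e, -1L)), end = e)
}

#' Default 16-frame, 40-minute dynamic FET-PET schedule
#'
#' Seven 10-s frames, three 30-s frames, one 2-min frame, three 5-min frames
#' and two 10-min frames: 16 frames covering 0--2380 s post injection.
#'
#' @return A [FrameSchedule-class] with 16 frames and total duration 2380 s.
#' @examples
#' sched <- defaultFrameSchedule()
#' nFrames(sched)
#' totalDuration(sched)
#' @export
defaultFrameSchedule <- function() {
  frameSchedule(c(rep(10, 7), rep(30, 3), 120, rep(300, 3), rep(600, 2)))
}

#' @describeIn FrameSchedule-class number of frames
#' @param x a \code{FrameSchedule}
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))

#' @describeIn FrameSchedule-class frame start times (seconds)
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) x@start)

#' @describeIn FrameSchedule-class frame end times (seconds)
#' @export
setMethod("frameEnds", "FrameSchedule", function(x) x@end)

#' @describeIn FrameSchedule-class frame durations (seconds)
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@end - x@start)

#' @describeIn FrameSchedule-class frame mid-times (seconds)
#' @export
setMethod("frameMids", "FrameSchedule", function(x) (x@start + x@end) / 2)

#' @describeIn FrameSchedule-class total scan duration (seconds)
#' @export
setMethod("totalDuration", "FrameSchedule", function(x) x@end[length(x@end)])

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, 0-%g s (%.1f min)\n",
              nFrames(object), totalDuration(object), totalDuration(object) / 60))
  cat("  durations (s):", paste(frameDurations(object), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# DynamicStudy
# ---------------------------------------------------------------------------

#' A dynamic PET study: 4D activity volume plus its frame schedule
#'
#' @slot volume4d 4D numeric array, dimensions (x, y, z, frame), activity in
#'   arbitrary units, all values non-negative.
#' @slot schedule the [FrameSchedule-class] of the acquisition.
#' @slot spacing numeric(3), voxel spacing in mm.
#'
#' @export
setClass("DynamicStudy",
         representation(volume4d = "array", schedule = "FrameSchedule",
                        spacing = "numeric"))

setValidity("DynamicStudy", function(object) {
  d <- dim(object@volume4d)
  if (length(d) != 4L) return("volume4d must be a 4D array (x, y, z, frame)")
  if (d[4L] != nFrames(object@schedule))
    return(sprintf("frame count mismatch: volume has %d frames, schedule %d",
                   d[4L], nFrames(object@schedule)))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (mm)")
  if (anyNA(object@volume4d) || min(object@volume4d) < 0)
    return("activities must be finite and non-negative")
  TRUE
})

#' Construct a DynamicStudy
#'
#' @param volume4d 4D array (x, y, z, frame) of non-negative activities.
#' @param schedule a [FrameSchedule-class].
#' @param spacing numeric(3) voxel spacing in mm (default the scanner grid
#'   2.03 x 2.03 x 2.43 mm).
#' @return A [DynamicStudy-class].
#' @export
dynamicStudy <- function(volume4d, schedule, spacing = c(2.03, 2.03, 2.43)) {
  new("DynamicStudy", volume4d = volume4d, schedule = schedule,
      spacing = as.numeric(spacing))
}

#' @describeIn DynamicStudy-class the 4D activity array
#' @param x a \code{DynamicStudy}
#' @export
setMethod("studyVolume", "DynamicStudy", function(x) x@volume4d)

#' @describeIn DynamicStudy-class the acquisition schedule
#' @export
setMethod("studySchedule", "DynamicStudy", function(x) x@schedule)

#' @describeIn DynamicStudy-class voxel spacing in mm
#' @export
setMethod("voxelSpacing", "DynamicStudy", function(x) x@spacing)

setMethod("show", "DynamicStudy", function(object) {
  d <- dim(object@volume4d)
  cat(sprintf("DynamicStudy: %d x %d x %d voxels, %d frames\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  spacing: %s mm; duration %.1f min\n",
              paste(format(object@spacing), collapse = " x "),
              totalDuration(object@schedule) / 60))
})

# ---------------------------------------------------------------------------
# ParametricImage
# ---------------------------------------------------------------------------

.parametricKinds <- c("TBR_5_15", "TBR_20_40", "TTP")

#' A 3D parametric map derived from a dynamic study
#'
#' Either a tumour-to-background-ratio summation image (`TBR_5_15`,
#' `TBR_20_40`) covering the whole grid, or a categorical time-to-peak map
#' (`TTP`) defined inside the tumour mask (NA elsewhere) whose voxel values
#' are the representative minutes of the six TTP categories.
#'
#' @slot data 3D numeric array.
#' @slot kind one of `"TBR_5_15"`, `"TBR_20_40"`, `"TTP"`.
#' @slot spacing numeric(3) voxel spacing in mm.
#'
#' @export
setClass("ParametricImage",
         representation(data = "array", kind = "character", spacing = "numeric"))

setValidity("ParametricImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!(object@kind %in% .parametricKinds))
    return(sprintf("kind must be one of %s", paste(.parametricKinds, collapse = ", ")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (mm)")
  v <- object@data[!is.na(object@data)]
  if (object@kind == "TTP") {
    if (length(v) && !all(v %in% ttpCategories()$representative_min))
      return("TTP values must be category representative minutes")
  } else {
    if (anyNA(object@data)) return("TBR images must not contain NA")
    if (length(v) && min(v) < 0) return("TBR values must be non-negative")
  }
  TRUE
})

#' Construct a ParametricImage
#'
#' @param data 3D numeric array.
#' @param kind one of `"TBR_5_15"`, `"TBR_20_40"`, `"TTP"`.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A validated [ParametricImage-class].
#' @export
parametricImage <- function(data, kind, spacing) {
  new("ParametricImage", data = data, kind = kind, spacing = as.numeric(spacing))
}

#' @describeIn ParametricImage-class the 3D value array
#' @param x a \code{ParametricImage}
#' @export
setMethod("imageData", "ParametricImage", function(x) x@data)

#' @describeIn ParametricImage-class the image kind
#' @export
setMethod("imageKind", "ParametricImage", function(x) x@kind)

#' @describeIn ParametricImage-class voxel spacing in mm
#' @export
setMethod("voxelSpacing", "ParametricImage", function(x) x@spacing)

setMethod("show", "ParametricImage", function(object) {
  d <- dim(object@data)
  rng <- range(object@data, na.rm = TRUE)
  cat(sprintf("ParametricImage <%s>: %d x %d x %d, values %.3g-%.3g\n",
              object@kind, d[1L], d[2L], d[3L], rng[1L], rng[2L]))
})

# ---------------------------------------------------------------------------
# LogisticModel
# ---------------------------------------------------------------------------

#' A fitted class-balanced logistic model over selected radiomic features
#'
#' Stores the selected feature names (in model order), the training-cohort
#' standardisation parameters applied before fitting, the coefficients theta
#' and intercept theta0 of P(y=1|x) = 1 / (1 + exp(-(theta0 + theta' x))),
#' the class weights used, and the 0.5 decision threshold.
#'
#' @slot features character vector of selected feature names.
#' @slot theta named numeric coefficient vector (one per feature).
#' @slot intercept numeric(1), theta0.
#' @slot classWeights named numeric(2), weights for classes "0" and "1".
#' @slot center,scale named numeric standardisation parameters (training
#'   mean and population standard deviation) for the selected features.
#' @slot threshold probability cut-off for a positive call (0.5).
#' @slot C inverse regularisation strength of the ridge-penalised fit.
#'
#' @export
setClass("LogisticModel",
         representation(features = "character", theta = "numeric",
                        intercept = "numeric", classWeights = "numeric",
                        center = "numeric", scale = "numeric",
                        threshold = "numeric", C = "numeric"))

setValidity("LogisticModel", function(object) {
  if (length(object@theta) != length(object@features))
    return("theta must have one coefficient per selected feature")
  if (length(object@intercept) != 1L) return("intercept must be a scalar")
  if (length(object@threshold) != 1L || object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie in (0, 1)")
  TRUE
})

#' @describeIn LogisticModel-class selected feature names
#' @param x a \code{LogisticModel}
#' @export
setMethod("selectedFeatures", "LogisticModel", function(x) x@features)

#' @describeIn LogisticModel-class coefficient vector theta
#' @param object a \code{LogisticModel}
#' @export
setMethod("coef", "LogisticModel", function(object) object@theta)

#' @describeIn LogisticModel-class intercept theta0
#' @export
setMethod("modelIntercept", "LogisticModel", function(x) x@intercept)

#' @describeIn LogisticModel-class class weights used during fitting
#' @export
setMethod("classWeights", "LogisticModel", function(x) x@classWeights)

setMethod("show", "LogisticModel", function(object) {
  cat(sprintf("LogisticModel: %d selected features, intercept %.4g\n",
              length(object@features), object@intercept))
  tab <- data.frame(feature = object@features, theta = unname(object@theta))
  print(tab, row.names = FALSE)
})

# ---------------------------------------------------------------------------
# EvaluationReport
# ---------------------------------------------------------------------------

#' Classifier performance metrics with bootstrap confidence intervals
#'
#' AUC, accuracy, sensitivity, specificity, PPV and NPV at the 0.5 threshold
#' (positive class: TERTp-mutation), with 95% percentile confidence intervals
#' from stratified non-parametric bootstrap resampling.
#'
#' @slot metrics named numeric point estimates.
#' @slot ciLower,ciUpper named numeric 95% CI bounds.
#' @slot nBootstrap number of bootstrap replicates.
#'
#' @export
setClass("EvaluationReport",
         representation(metrics = "numeric", ciLower = "numeric",
                        ciUpper = "numeric", nBootstrap = "integer"))

setValidity("EvaluationReport", function(object) {
  need <- c("auc", "accuracy", "sensitivity", "specificity", "ppv", "npv")
  if (!all(need %in% names(object@metrics)))
    return("metrics must contain auc, accuracy, sensitivity, specificity, ppv, npv")
  ok <- !is.na(object@metrics)
  if (any(object@metrics[ok] < 0 | object@metrics[ok] > 1))
    return("all metrics must lie in [0, 1]")
  TRUE
})

#' @describeIn EvaluationReport-class metrics as a data.frame with CI bounds
#' @param x an \code{EvaluationReport}
#' @export
setMethod("metricTable", "EvaluationReport", function(x) {
  data.frame(metric = names(x@metrics), value = unname(x@metrics),
             ci_lower = unname(x@ciLower[names(x@metrics)]),
             ci_upper = unname(x@ciUpper[names(x@metrics)]))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%d bootstrap replicates):\n", object@nBootstrap))
  tab <- metricTable(object)
  tab$value <- sprintf("%.3f", tab$value)
  tab$ci95 <- sprintf("(%.3f-%.3f)", tab$ci_lower, tab$ci_upper)
  print(tab[, c("metric", "value", "ci95")], row.names = FALSE)
})
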