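#' @include AllClasses.R
NULL

#' The six time-to-peak categories
#'
#' Categories are defined on the minute of peak uptake: (1) < 5 min,
#' (2) 5--10, (3) 10--15, (4) 15--20, (5) 20--30, (6) 30--40 min. Voxels of a
#' TTP parametric image carry the category midpoint in minutes, so that a
#' fixed 5-min bin width discretises the six categories to distinct levels.
#'
#' @return data.frame with columns \code{ordinal}, \code{lower_min},
#'   \code{upper_min}, \code{representative_min}.
#' @export
ttpCategories <- function() {
  data.frame(ordinal = 1:6,
             lower_min = c(0, 5, 10, 15, 20, 30),
             upper_min = c(5, 10, 15, 20, 30, 40),
             representative_min = c(2.5, 7.5, 12.5, 17.5, 25, 35))
}

#' Frames whose mid-time falls in a minute window
#'
#' Frame selection for summation windows uses the frame mid-time in
#' \code{[t0, t1)} minutes: the printed 16-frame schedule does not align with
#' the nominal 5/15/20/40-min cuts (frames end at 4.67/14.67/19.67/39.67
#' min), and mid-time selection reproduces the intended two-frame windows.
#'
#' @param schedule a [FrameSchedule-class].
#' @param windowMin numeric(2) window in minutes.
#' @return integer vector of frame indices.
#' @export
framesInWindow <- function(schedule, windowMin) {
  mids <- frameMids(schedule) / 60
  which(mids >= windowMin[1L] & mids < windowMin[2L])
}

#' Duration-weighted summation image over a time window
#'
#' @param study a [DynamicStudy-class].
#' @param windowMin numeric(2) window in minutes post injection; frames are
#'   selected by mid-time (see [framesInWindow()]).
#' @return 3D array: the duration-weighted mean activity of the selected
#'   frames.
#' @export
summationImage <- function(study, windowMin) {
  stopifnot(is(study, "DynamicStudy"), length(windowMin) == 2L)
  sched <- studySchedule(study)
  idx <- framesInWindow(sched, windowMin)
  if (!length(idx))
    stop(sprintf("no frames with mid-time in [%g, %g) min", windowMin[1L], windowMin[2L]))
  w <- frameDurations(sched)[idx]
  vol <- studyVolume(study)
  dims <- dim(vol)[1:3]
  out <- array(0, dims)
  for (k in seq_along(idx)) out <- out + w[k] * vol[, , , idx[k]]
  out / sum(w)
}

#' Mean activity over a background mask
#'
#' @param image 3D array (or [ParametricImage-class]).
#' @param background logical array of the same shape; must be non-empty.
#' @return scalar arithmetic mean over masked voxels.
#' @export
backgroundMean <- function(image, background) {
  if (is(image, "ParametricImage")) image <- imageData(image)
  stopifnot(identical(dim(image), dim(background)))
  if (!any(background)) stop("background mask is empty")
  mean(image[background])
}

#' Tumour-to-background-ratio image
#'
#' Voxel-wise division of a summation image by the mean background activity.
#'
#' @param image 3D summation image (array).
#' @param bg positive scalar background mean (see [backgroundMean()]).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param kind `"TBR_5_15"` or `"TBR_20_40"`.
#' @return A [ParametricImage-class] of the requested kind.
#' @export
tbrImage <- function(image, bg, spacing, kind = c("TBR_20_40", "TBR_5_15")) {
  kind <- match.arg(kind)
  if (!is.numeric(bg) || length(bg) != 1L || bg <= 0)
    stop("background mean must be a positive scalar")
  parametricImage(image / bg, kind, spacing)
}

#' Segment the tumour VOI at a TBR threshold
#'
#' Thresholds the late (20--40 min) TBR image at \code{threshold}
#' (inclusive, >=) and keeps the largest 26-connected component. An empty
#' result signals a FET-negative study (such studies are excluded from
#' analysis) via a condition of class \code{"dynFET_fet_negative"}.
#'
#' @param tbr2040 a [ParametricImage-class] of kind `TBR_20_40`.
#' @param threshold TBR threshold, default 1.6.
#' @return logical tumour mask.
#' @export
segmentTumour <- function(tbr2040, threshold = 1.6) {
  stopifnot(is(tbr2040, "ParametricImage"))
  if (imageKind(tbr2040) != "TBR_20_40")
    stop("segmentation requires a TBR_20_40 image")
  above <- imageData(tbr2040) >= threshold
  if (!any(above))
    stop(errorCondition(
      sprintf("FET-negative study: no voxel reaches TBR >= %g", threshold),
      class = "dynFET_fet_negative"))
  labels <- labelComponents(above, 26L)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

#' Classify one voxel time-activity curve into a TTP category
#'
#' Two-step rule: (a) fit an ordinary least-squares slope of frame activity
#' against frame mid-time over the late frames (mid-times in [15, 40) min);
#' a strictly positive slope assigns category 6. (b) Otherwise take the
#' arg-max frame among frames ending after the first 2.7 min (end-time
#' > 162 s, excluding the early blood-flush frames) -- ties broken toward the
#' earliest frame -- and map its mid-time to the category containing it.
#'
#' @param tac numeric vector, one activity per frame.
#' @param schedule a [FrameSchedule-class] of matching length.
#' @return integer TTP category ordinal in 1..6.
#' @export
classifyVoxelTTP <- function(tac, schedule) {
  stopifnot(length(tac) == nFrames(schedule))
  cls <- classifyTTPMatrix(matrix(tac, nrow = 1L), schedule)
  cls[1L]
}

# Vectorised TTP classification: tacs is nVoxel x nFrame.
classifyTTPMatrix <- function(tacs, schedule) {
  midsMin <- frameMids(schedule) / 60
  late <- which(midsMin >= 15 & midsMin < 40)
  if (length(late) < 2L)
    stop("late-slope fit requires at least 2 frames with mid-time in [15, 40) min")
  tl <- midsMin[late]
  y <- tacs[, late, drop = FALSE]
  tc <- tl - mean(tl)
  slope <- as.vector(y %*% tc) / sum(tc^2)

  eligible <- which(frameEnds(schedule) > 162)
  if (!length(eligible)) stop("no frames remain after the 2.7-min exclusion")
  sub <- tacs[, eligible, drop = FALSE]
  am <- max.col(sub, ties.method = "first")
  peakMin <- midsMin[eligible][am]
  cats <- ttpCategories()
  cat <- findInterval(peakMin, c(cats$lower_min, 40), rightmost.closed = FALSE)
  cat <- pmin(pmax(cat, 1L), 6L)
  ifelse(slope > 0, 6L, cat)
}

#' Time-to-peak parametric image
#'
#' Applies [classifyVoxelTTP()] to every voxel inside the tumour mask and
#' writes the category's representative minute (2.5, 7.5, 12.5, 17.5, 25,
#' 35); voxels outside the mask are NA.
#'
#' @param study a [DynamicStudy-class].
#' @param tumour non-empty logical tumour mask.
#' @return A [ParametricImage-class] of kind `TTP`.
#' @export
ttpImage <- function(study, tumour) {
  stopifnot(is(study, "DynamicStudy"))
  vol <- studyVolume(study)
  dims <- dim(vol)[1:3]
  stopifnot(identical(dim(tumour), dims))
  idx <- which(tumour)
  if (!length(idx)) stop("tumour mask is empty")
  nF <- dim(vol)[4L]
  tacs <- matrix(vol, ncol = nF)[idx, , drop = FALSE]
  cat <- classifyTTPMatrix(tacs, studySchedule(study))
  rep_min <- ttpCategories()$representative_min
  out <- array(NA_real_, dims)
  out[idx] <- rep_min[cat]
  parametricImage(out, "TTP", voxelSpacing(study))
}

#' Full parametric-imaging stage for one study
#'
#' Computes the background-normalised TBR_5-15 and TBR_20-40 summation
#' images, segments the tumour at the TBR threshold (or uses the supplied
#' mask), and derives the TTP image inside the tumour.
#'
#' @param study a [DynamicStudy-class].
#' @param background logical background VOI mask.
#' @param tumour optional logical tumour mask; when NULL the tumour is
#'   auto-segmented from the TBR_20-40 image.
#' @param threshold TBR segmentation threshold (default 1.6).
#' @return list with \code{tbr0515}, \code{tbr2040}, \code{ttp}
#'   ([ParametricImage-class]), \code{tumourMask} and the background means.
#' @export
parametricImages <- function(study, background, tumour = NULL, threshold = 1.6) {
  sum0515 <- summationImage(study, c(5, 15))
  sum2040 <- summationImage(study, c(20, 40))
  bg0515 <- backgroundMean(sum0515, background)
  bg2040 <- backgroundMean(sum2040, background)
  sp <- voxelSpacing(study)
  tbr0515 <- tbrImage(sum0515, bg0515, sp, "TBR_5_15")
  tbr2040 <- tbrImage(sum2040, bg2040, sp, "TBR_20_40")
  if (is.null(tumour)) tumour <- segmentTumour(tbr2040, threshold)
  list(tbr0515 = tbr0515, tbr2040 = tbr2040,
       ttp = ttpImage(study, tumour), tumourMask = tumour,
       backgroundMeans = c(TBR_5_15 = bg0515, TBR_20_40 = bg2040),
       threshold = threshold)
}
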