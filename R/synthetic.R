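#' @include AllClasses.R
NULL

#' Kinetic parameters of a voxel time-activity curve
#'
#' The continuous kinetic model is a piecewise-linear "tent": activity rises
#' linearly from \code{baseline} at t = 0 to \code{amplitude} at
#' \code{peakTimeMin}, then changes linearly with \code{washoutSlope}
#' (activity per minute), floored at \code{baseline}. A negative slope gives
#' the early-peak/washout archetype of aggressive gliomas; a positive slope
#' encodes the slowly increasing uptake of less aggressive kinetics.
#'
#' @param amplitude peak activity (arbitrary units), \code{>= baseline}.
#' @param peakTimeMin time of the peak in minutes, in (0, 40).
#' @param washoutSlope post-peak slope in activity/min (\code{<= 0} for
#'   washout curves, \code{> 0} for late-increasing curves).
#' @param baseline baseline activity, \code{>= 0}.
#' @param noiseSd standard deviation of additive per-frame Gaussian noise.
#' @return A validated list of class \code{KineticParams}.
#' @export
kineticParams <- function(amplitude, peakTimeMin, washoutSlope = 0,
                          baseline = 0, noiseSd = 0) {
  stopifnot(is.numeric(amplitude), is.numeric(peakTimeMin))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (baseline < 0) stop("baseline must be non-negative")
  if (amplitude < baseline) stop("amplitude must be >= baseline")
  if (peakTimeMin <= 0 || peakTimeMin >= 40)
    stop("peakTimeMin must lie in (0, 40) minutes")
  structure(list(amplitude = amplitude, peakTimeMin = peakTimeMin,
                 washoutSlope = washoutSlope, baseline = baseline,
                 noiseSd = noiseSd), class = "KineticParams")
}

# Exact frame-duration-weighted averages of the continuous tent curve for
# vectors of parameters (one entry per voxel). Times in seconds internally;
# slopes are per minute. Returns an nVoxel x nFrame matrix.
tentFrameAverages <- function(amplitude, peakTimeMin, washoutSlope, baseline,
                              schedule) {
  u <- frameStarts(schedule); v <- frameEnds(schedule)
  nV <- length(amplitude); nF <- nFrames(schedule)
  tp <- peakTimeMin * 60
  s <- washoutSlope / 60                      # activity per second
  A <- amplitude; b <- baseline

  fEval <- function(t) {
    # t: nV x nF matrix of times (seconds)
    rise <- b + (A - b) * t / tp
    post <- A + s * (t - tp)
    val <- ifelse(t <= tp, rise, pmax(b, post))
    val
  }
  U <- matrix(u, nV, nF, byrow = TRUE)
  V <- matrix(v, nV, nF, byrow = TRUE)
  # interior breakpoints: the peak and (for washout curves) the floor crossing
  t1 <- pmin(pmax(tp, U), V)
  tStar <- ifelse(s < 0, tp + (b - A) / s, Inf)
  t2 <- pmin(pmax(pmin(tStar, Inf), t1), V)
  seg <- function(a, bb) (fEval(a) + fEval(bb)) / 2 * (bb - a)
  int <- seg(U, t1) + seg(t1, t2) + seg(t2, V)
  int / (V - U)
}

#' Simulate a frame-averaged time-activity curve
#'
#' Returns one activity value per frame: the frame-duration-weighted average
#' of the continuous tent curve (mirroring how a scanner integrates counts
#' over a frame), plus zero-mean Gaussian noise, clipped at zero.
#'
#' @param params a [kineticParams()] object.
#' @param schedule a [FrameSchedule-class].
#' @param seed integer seed for the noise stream.
#' @return numeric vector of per-frame activities (all \code{>= 0}).
#' @examples
#' tac <- simulateTAC(kineticParams(3, 7, -0.05, 1), defaultFrameSchedule(), 1)
#' @export
simulateTAC <- function(params, schedule, seed = 1L) {
  stopifnot(inherits(params, "KineticParams"), is(schedule, "FrameSchedule"))
  mu <- tentFrameAverages(params$amplitude, params$peakTimeMin,
                          params$washoutSlope, params$baseline, schedule)[1L, ]
  if (params$noiseSd > 0)
    mu <- withSeed(seed, mu + rnorm(length(mu), sd = params$noiseSd))
  pmax(mu, 0)
}

#' Specification of a synthetic dynamic-PET cohort
#'
#' Defines the study conditions for the phantom generator: cohort size, class
#' balance, grid geometry, the master seed, and the \code{effect} parameter
#' that controls how strongly the TERTp-mutant label shifts the spatial
#' heterogeneity of voxel kinetics. \code{effect = 0} makes the two classes
#' statistically identical (a null cohort).
#'
#' @param nPatients number of patients (>= 2).
#' @param wildtypeFraction proportion of TERTp-wildtype patients in [0, 1].
#' @param gridShape integer(3) voxels per axis.
#' @param voxelSpacing numeric(3) spacing in mm (scanner default
#'   2.03 x 2.03 x 2.43).
#' @param seed master integer seed; all label, geometry, kinetics and noise
#'   streams are derived from it.
#' @param effect separation parameter (>= 0) for the label-dependent kinetic
#'   heterogeneity shift.
#' @param noiseSd per-frame additive noise standard deviation (activity
#'   units; background activity is 1).
#' @return A validated list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(nPatients, wildtypeFraction = 0.2,
                       gridShape = c(40L, 40L, 24L),
                       voxelSpacing = c(2.03, 2.03, 2.43),
                       seed = 1L, effect = 1, noiseSd = 0.05) {
  stopifnot(nPatients >= 2, wildtypeFraction >= 0, wildtypeFraction <= 1,
            length(gridShape) == 3L, all(gridShape >= 8L),
            length(voxelSpacing) == 3L, all(voxelSpacing > 0),
            effect >= 0, noiseSd >= 0)
  nWT <- round(nPatients * wildtypeFraction)
  if (wildtypeFraction > 0 && wildtypeFraction < 1 &&
      (nWT < 1L || nWT > nPatients - 1L))
    stop("cohort must contain at least one patient per class")
  structure(list(nPatients = as.integer(nPatients),
                 wildtypeFraction = wildtypeFraction,
                 gridShape = as.integer(gridShape),
                 voxelSpacing = as.numeric(voxelSpacing),
                 seed = as.integer(seed), effect = effect, noiseSd = noiseSd),
            class = "CohortSpec")
}

#' Ground-truth labels of a synthetic cohort
#'
#' Exactly \code{round(nPatients * wildtypeFraction)} patients are wildtype
#' (label 0); the rest are TERTp-mutant (label 1). The order is shuffled by a
#' seed-derived stream, so counts are exact for every seed.
#'
#' @param spec a [cohortSpec()].
#' @return integer vector of 0/1 labels, one per patient.
#' @export
phantomLabels <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  nWT <- round(spec$nPatients * spec$wildtypeFraction)
  withSeed(deriveSeed(spec$seed, "labels"),
           sample(c(rep(0L, nWT), rep(1L, spec$nPatients - nWT))))
}

# The fixed crescent-shaped background VOI in the contralateral (high-x)
# half of the grid: the set difference of two overlapping spheres.
crescentBackgroundMask <- function(gridShape) {
  nx <- gridShape[1L]; ny <- gridShape[2L]; nz <- gridShape[3L]
  x <- slice.index(array(0, gridShape), 1L)
  y <- slice.index(array(0, gridShape), 2L)
  z <- slice.index(array(0, gridShape), 3L)
  r <- 0.20 * nx
  dA <- sqrt((x - 0.74 * nx)^2 + (y - 0.50 * ny)^2 + ((z - 0.50 * nz) * 1.4)^2)
  dB <- sqrt((x - 0.60 * nx)^2 + (y - 0.50 * ny)^2 + ((z - 0.50 * nz) * 1.4)^2)
  dA <= r & dB > r
}

# Frame mid-times (minutes) of the six argmax-eligible frames of the default
# schedule, used as planted peak times for TTP categories 1..5.
.categoryPeakTimesMin <- c(220, 430, 730, 1030, 1480) / 60

#' Generate one synthetic patient
#'
#' Deterministic given \code{spec} and the patient index: an ellipsoidal
#' tumour whose voxels draw tent-curve kinetics from a label-dependent
#' mixture over the six TTP categories, a crescent-shaped flat-uptake
#' background VOI in the contralateral hemisphere, and constant unit-activity
#' tissue elsewhere. The tumour baseline is 2.0 with background 1.0, so every
#' tumour voxel's 20--40 min TBR is >= 1.6 under zero noise.
#'
#' Wildtype tumours concentrate on one dominant TTP category (mixing
#' probability 0.12); mutant tumours mix in other categories with
#' probability \code{min(0.12 + 0.38 * effect, 0.95)}.
#'
#' @param spec a [cohortSpec()].
#' @param i patient index in \code{1:nPatients}.
#' @param label optional 0/1 label; defaults to \code{phantomLabels(spec)[i]}.
#' @return list with elements \code{study} ([DynamicStudy-class]),
#'   \code{tumourMask}, \code{backgroundMask} (logical arrays), \code{label},
#'   and \code{truth} (dominant category, mixing probability, per-voxel
#'   planted categories).
#' @export
phantomPatient <- function(spec, i, label = NULL) {
  stopifnot(inherits(spec, "CohortSpec"), i >= 1L, i <= spec$nPatients)
  if (is.null(label)) label <- phantomLabels(spec)[i]
  dims <- spec$gridShape
  nF <- 16L
  schedule <- defaultFrameSchedule()

  geom <- withSeed(deriveSeed(spec$seed, "geom", i), {
    list(centre = c(runif(1, 0.28, 0.38) * dims[1L],
                    runif(1, 0.42, 0.58) * dims[2L],
                    runif(1, 0.42, 0.58) * dims[3L]),
         semi = c(runif(1, 4, 6), runif(1, 4, 6), runif(1, 3, 4.5)))
  })
  x <- slice.index(array(0, dims), 1L)
  y <- slice.index(array(0, dims), 2L)
  z <- slice.index(array(0, dims), 3L)
  tumour <- ((x - geom$centre[1L]) / geom$semi[1L])^2 +
            ((y - geom$centre[2L]) / geom$semi[2L])^2 +
            ((z - geom$centre[3L]) / geom$semi[3L])^2 <= 1
  if (!any(tumour)) stop("tumour ellipsoid contains no voxels")
  lo <- geom$centre - geom$semi; hi <- geom$centre + geom$semi
  if (any(lo < 1) || any(hi > dims)) stop("tumour does not fit inside the grid")
  background <- crescentBackgroundMask(dims)
  if (any(tumour & background)) stop("tumour overlaps the background VOI")

  tIdx <- which(tumour)
  nT <- length(tIdx)
  mixing <- if (label == 1L) min(0.12 + 0.38 * spec$effect, 0.95) else 0.12
  kin <- withSeed(deriveSeed(spec$seed, "kinetics", i), {
    dominant <- sample(1:6, 1L)
    cats <- ifelse(runif(nT) < mixing, sample(1:6, nT, replace = TRUE), dominant)
    washout <- cats <= 5L
    A <- ifelse(washout, runif(nT, 2.6, 3.6), runif(nT, 2.2, 2.6))
    tp <- ifelse(washout, .categoryPeakTimesMin[pmin(cats, 5L)], runif(nT, 1, 3))
    s <- ifelse(washout, -runif(nT, 0.028, 0.040) * A, runif(nT, 0.010, 0.020) * A)
    list(dominant = dominant, cats = cats, A = A, tp = tp, s = s)
  })

  vol <- array(1, c(dims, nF))
  tumourTacs <- tentFrameAverages(kin$A, kin$tp, kin$s, rep(2, nT), schedule)
  bIdx <- which(background)
  frameOffsets <- (seq_len(nF) - 1L) * prod(dims)
  for (f in seq_len(nF)) vol[tIdx + frameOffsets[f]] <- tumourTacs[, f]
  if (spec$noiseSd > 0) {
    noisy <- c(tIdx, bIdx)
    vol[rep(noisy, nF) + rep(frameOffsets, each = length(noisy))] <-
      withSeed(deriveSeed(spec$seed, "noise", i),
               pmax(vol[rep(noisy, nF) + rep(frameOffsets, each = length(noisy))] +
                      rnorm(length(noisy) * nF, sd = spec$noiseSd), 0))
  }
  list(study = dynamicStudy(vol, schedule, spec$voxelSpacing),
       tumourMask = tumour, backgroundMask = background,
       label = as.integer(label),
       truth = list(dominant = kin$dominant, mixing = mixing,
                    categories = kin$cats))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper around [phantomPatient()]; for large cohorts prefer
#' streaming patients one at a time to bound memory.
#'
#' @param spec a [cohortSpec()].
#' @return list of per-patient lists (see [phantomPatient()]); the label
#'   vector is attached as attribute \code{"labels"}.
#' @export
generatePhantom <- function(spec) {
  labels <- phantomLabels(spec)
  out <- lapply(seq_len(spec$nPatients), function(i)
    phantomPatient(spec, i, labels[i]))
  attr(out, "labels") <- labels
  out
}
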