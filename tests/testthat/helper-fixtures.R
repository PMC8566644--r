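# Shared builders for small deterministic test objects.

# A study whose every voxel follows the supplied per-frame values.
uniformStudy <- function(frameValues, dims = c(4L, 4L, 3L),
                         schedule = defaultFrameSchedule(),
                         spacing = c(2.03, 2.03, 2.43)) {
  vol <- array(rep(frameValues, each = prod(dims)), c(dims, length(frameValues)))
  dynamicStudy(vol, schedule, spacing)
}

# Independent numeric oracle for the tent-curve frame averages: dense
# trapezoidal integration of the piecewise-linear curve.
numericTentAverages <- function(amplitude, peakTimeMin, washoutSlope, baseline,
                                schedule, nGrid = 4000L) {
  tp <- peakTimeMin * 60
  s <- washoutSlope / 60
  f <- function(t) {
    ifelse(t <= tp,
           baseline + (amplitude - baseline) * t / tp,
           pmax(baseline, amplitude + s * (t - tp)))
  }
  mapply(function(u, v) {
    tt <- seq(u, v, length.out = nGrid)
    y <- f(tt)
    sum((y[-1] + y[-nGrid]) / 2 * diff(tt)) / (v - u)
  }, frameStarts(schedule), frameEnds(schedule))
}

# Independent re-implementation of the TTP classification rule, operating on
# a numeric frame-average vector (used as the oracle for the package rule).
oracleTTPCategory <- function(frameValues, schedule) {
  mids <- frameMids(schedule) / 60
  late <- mids >= 15 & mids < 40
  ft <- mids[late]; fv <- frameValues[late]
  slope <- sum((ft - mean(ft)) * (fv - mean(fv))) / sum((ft - mean(ft))^2)
  if (slope > 0) return(6L)
  elig <- which(frameEnds(schedule) > 162)
  peakMid <- mids[elig][which.max(frameValues[elig])]
  bounds <- c(0, 5, 10, 15, 20, 30, 40)
  max(which(peakMid >= bounds[1:6]))
}
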