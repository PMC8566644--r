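#' @include discretize.R
NULL

#' First-order (intensity histogram) features
#'
#' The 18 standard first-order features. Energy and root-mean-square use the
#' raw intensities (no intensity shift); TotalEnergy multiplies Energy by the
#' voxel volume; Entropy and Uniformity are computed on the fixed-bin-width
#' discretised histogram; percentiles use linear interpolation; variance,
#' skewness and kurtosis use population (divisor-N) moments, with kurtosis
#' uncorrected (a Gaussian scores 3). Degenerate constant regions report
#' skewness and kurtosis of 0.
#'
#' @param values numeric vector of masked intensities (>= 1 voxel).
#' @param binWidth fixed bin width for the histogram-based features.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return named numeric vector of 18 features, keys \code{firstorder.*}.
#' @export
firstOrderFeatures <- function(values, binWidth, spacing) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("first-order features require a non-empty mask")
  n <- length(v)
  lev <- discretizeIntensities(v, binWidth)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  q <- quantile(v, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  mid <- v[v >= q[1L] & v <= q[4L]]
  c(firstorder.Energy = sum(v^2),
    firstorder.TotalEnergy = prod(spacing) * sum(v^2),
    firstorder.Entropy = -sum(p * log2(p)),
    firstorder.Minimum = min(v),
    firstorder.10Percentile = q[1L],
    firstorder.90Percentile = q[4L],
    firstorder.Maximum = max(v),
    firstorder.Mean = mu,
    firstorder.Median = median(v),
    firstorder.InterquartileRange = q[3L] - q[2L],
    firstorder.Range = max(v) - min(v),
    firstorder.MeanAbsoluteDeviation = mean(abs(v - mu)),
    firstorder.RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    firstorder.RootMeanSquared = sqrt(mean(v^2)),
    firstorder.Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder.Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder.Variance = m2,
    firstorder.Uniformity = sum(p^2))
}

#' @importFrom stats median
NULL
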