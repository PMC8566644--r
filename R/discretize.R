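#' @include AllClasses.R
NULL

#' Fixed bin width from the mean interquartile range divided by 4
#'
#' The per-patient interquartile range (Q3 - Q1, quartiles by linear
#' interpolation between closest order statistics) of the masked intensities
#' is averaged over patients and divided by 4. This reproduces the
#' data-derived fixed bin widths of the TBR images (0.18 for TBR_5-15, 0.13
#' for TBR_20-40 on the original cohort); TTP images use a fixed 5-min width
#' instead, the smallest frame duration spanned by a TTP category.
#'
#' @param valueSets list of numeric vectors, one per patient (each with at
#'   least 4 values).
#' @return scalar bin width.
#' @export
iqr4BinWidth <- function(valueSets) {
  if (!is.list(valueSets) || !length(valueSets))
    stop("valueSets must be a non-empty list of per-patient intensity vectors")
  iqrs <- vapply(valueSets, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 4L) stop("each intensity collection needs at least 4 values")
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2L] - q[1L]
  }, numeric(1L))
  mean(iqrs) / 4
}

#' Discretise masked intensities with a fixed bin width
#'
#' Bin index of value v is \code{floor((v - min(values)) / binWidth) + 1}:
#' bins are anchored at the masked minimum, which maps to level 1.
#'
#' @param values numeric vector of masked intensities.
#' @param binWidth positive bin width in intensity units.
#' @return integer vector of grey levels; the number of occupied levels is
#'   attached as attribute \code{"Ng"}.
#' @export
discretizeIntensities <- function(values, binWidth) {
  if (!is.numeric(binWidth) || length(binWidth) != 1L || binWidth <= 0)
    stop("binWidth must be a positive scalar")
  v <- values[!is.na(values)]
  if (!length(v)) stop("no values to discretise")
  lev <- as.integer(floor((values - min(v)) / binWidth) + 1)
  structure(lev, Ng = length(unique(lev[!is.na(lev)])))
}
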