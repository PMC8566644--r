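#' @include firstorder.R shape.R texture.R resample.R
NULL

.featureClassSizes <- c(firstorder = 18L, shape = 14L, glcm = 24L,
                        glrlm = 16L, glszm = 16L, gldm = 14L, ngtdm = 5L)

#' Extract the full 107-feature radiomics vector
#'
#' Pipeline: resample image and mask to an isotropic grid (trilinear /
#' nearest-neighbour), discretise the masked intensities with the fixed bin
#' width, then compute 18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16
#' GLSZM, 14 GLDM and 5 NGTDM features (107 in total, no image filters).
#'
#' @param image a [ParametricImage-class] (or 3D array with \code{spacing}).
#' @param mask logical tumour mask on the same grid.
#' @param binWidth fixed intensity bin width (e.g. 0.18 for TBR_5-15, 0.13
#'   for TBR_20-40, 5 min for TTP images).
#' @param targetMm isotropic resampling target in mm (default 2.03).
#' @param spacing numeric(3), required when \code{image} is a plain array.
#' @return named numeric vector of 107 features (keys \code{class.Name});
#'   the bin width and resampling target are attached as attributes
#'   \code{"binWidth"} and \code{"targetMm"}.
#' @examples
#' img <- array(runif(1000), c(10, 10, 10))
#' msk <- array(FALSE, c(10, 10, 10)); msk[3:8, 3:8, 3:8] <- TRUE
#' fv <- extractRadiomics(img, msk, binWidth = 0.1, spacing = rep(2.03, 3))
#' length(fv)  # 107
#' @export
extractRadiomics <- function(image, mask, binWidth, targetMm = 2.03,
                             spacing = NULL) {
  rs <- tryCatch(resampleIsotropic(image, mask, targetMm, spacing),
                 error = function(e) stop("resampling: ", conditionMessage(e)))
  vals <- rs$data[rs$mask]
  if (!length(vals) || all(is.na(vals)))
    stop("discretisation: no intensities inside the resampled mask")
  lev <- tryCatch(discretizeIntensities(vals, binWidth),
                  error = function(e) stop("discretisation: ", conditionMessage(e)))
  levArr <- array(NA_integer_, dim(rs$data))
  levArr[rs$mask] <- lev
  out <- c(firstOrderFeatures(vals, binWidth, rs$spacing),
           shapeFeatures(rs$mask, rs$spacing),
           glcmFeatures(levArr),
           glrlmFeatures(levArr),
           glszmFeatures(levArr),
           gldmFeatures(levArr),
           ngtdmFeatures(levArr))
  stopifnot(length(out) == 107L, !anyNA(names(out)))
  attr(out, "binWidth") <- binWidth
  attr(out, "targetMm") <- targetMm
  out
}

#' Names of the 107 radiomic features
#'
#' @return character vector of the 107 feature keys in extraction order.
#' @export
radiomicsFeatureNames <- function() {
  img <- array(rep(c(1, 2, 3, 4), 16), c(4, 4, 4))
  msk <- array(TRUE, c(4, 4, 4))
  names(extractRadiomics(img, msk, binWidth = 1, spacing = rep(2.03, 3)))
}

#' Build a cohort feature table
#'
#' Applies [extractRadiomics()] to one parametric image per patient and
#' stacks the 107-feature vectors into a patients x features matrix.
#'
#' @param images list of [ParametricImage-class] (one per patient).
#' @param masks list of logical tumour masks.
#' @param binWidth fixed bin width shared by the cohort (see
#'   [iqr4BinWidth()]).
#' @param targetMm isotropic resampling target in mm.
#' @return numeric matrix, rownames patient ids, colnames the 107 features;
#'   bin width recorded in attribute \code{"binWidth"}.
#' @export
featureTable <- function(images, masks, binWidth, targetMm = 2.03) {
  stopifnot(length(images) == length(masks))
  rows <- lapply(seq_along(images), function(i)
    extractRadiomics(images[[i]], masks[[i]], binWidth, targetMm))
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(images) %||% sprintf("P%03d", seq_along(images))
  attr(tab, "binWidth") <- binWidth
  tab
}
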