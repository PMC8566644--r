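#' @include AllClasses.R
NULL

#' Resample an image and mask to an isotropic grid
#'
#' Trilinear interpolation for the image and nearest-neighbour for the mask,
#' onto an isotropic grid aligned at the original origin (the centre of the
#' first voxel). The new axis length is \code{floor(n * spacing / target)}
#' voxels (at least 1). NA voxels (e.g. outside the TTP tumour mask) are
#' excluded from the interpolation by renormalising the trilinear weights
#' over the finite corners; a point with no finite corner stays NA.
#'
#' @param image a [ParametricImage-class] or 3D array.
#' @param mask logical array on the same grid.
#' @param targetMm isotropic target spacing in mm (default 2.03).
#' @param spacing numeric(3) source spacing, required when \code{image} is a
#'   plain array.
#' @return list with \code{data} (3D array), \code{mask} (logical array) and
#'   \code{spacing} (numeric(3), isotropic).
#' @export
resampleIsotropic <- function(image, mask, targetMm = 2.03, spacing = NULL) {
  if (is(image, "ParametricImage")) {
    spacing <- voxelSpacing(image)
    image <- imageData(image)
  }
  stopifnot(is.array(image), length(dim(image)) == 3L,
            identical(dim(image), dim(mask)),
            length(spacing) == 3L, all(spacing > 0), targetMm > 0)
  dims <- dim(image)
  if (!any(mask)) stop("resampled mask is empty")
  if (all(abs(spacing - targetMm) < 1e-12))
    return(list(data = image, mask = mask, spacing = rep(targetMm, 3L)))
  newDims <- pmax(1L, as.integer(floor(dims * spacing / targetMm)))
  # 0-based source voxel-index positions of the new voxel centres
  pos <- lapply(1:3, function(a) (seq_len(newDims[a]) - 1L) * targetMm / spacing[a])

  lo <- lapply(1:3, function(a) pmin(pmax(floor(pos[[a]]), 0), dims[a] - 1L))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, dims[a] - 1L))
  w <- lapply(1:3, function(a) pmin(pmax(pos[[a]] - lo[[a]], 0), 1))

  linIndex <- function(ix, iy, iz)
    outer(outer(ix + 1L, dims[1L] * iy, `+`), dims[1L] * dims[2L] * iz, `+`)

  acc <- array(0, newDims)
  wacc <- array(0, newDims)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    vals <- array(image[linIndex(if (cx) hi[[1L]] else lo[[1L]],
                                 if (cy) hi[[2L]] else lo[[2L]],
                                 if (cz) hi[[3L]] else lo[[3L]])], newDims)
    wx <- if (cx) w[[1L]] else 1 - w[[1L]]
    wy <- if (cy) w[[2L]] else 1 - w[[2L]]
    wz <- if (cz) w[[3L]] else 1 - w[[3L]]
    wt <- outer(outer(wx, wy), wz)
    fin <- is.finite(vals)
    acc[fin] <- acc[fin] + (wt * vals)[fin]
    wacc[fin] <- wacc[fin] + wt[fin]
  }
  out <- array(NA_real_, newDims)
  ok <- wacc > 0
  out[ok] <- acc[ok] / wacc[ok]

  nn <- lapply(1:3, function(a) pmin(pmax(round(pos[[a]]), 0), dims[a] - 1L))
  newMask <- array(mask[linIndex(nn[[1L]], nn[[2L]], nn[[3L]])], newDims)
  if (!any(newMask)) stop("resampled mask is empty")
  list(data = out, mask = newMask, spacing = rep(targetMm, 3L))
}
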