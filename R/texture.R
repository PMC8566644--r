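#' @include utils.R
NULL

.EPS <- 2.2e-16

# Padded-copy state shared by the neighbourhood scans: the level array with
# a one-voxel NA border, the masked voxel indices into it, their levels, and
# the 26 linear-index neighbour offsets.
.paddedLevels <- function(levels) {
  pv <- padArray(levels, NA_integer_)
  idx <- which(!is.na(pv))
  list(pv = pv, idx = idx, lv = pv[idx],
       offs = paddedOffsets(dim(pv), 26L),
       dirs = uniqueDirections13())
}

.dirOffset <- function(st, d) {
  off <- st$dirs[d, ]
  pd <- dim(st$pv)
  off[1L] + pd[1L] * (off[2L] + pd[2L] * off[3L])
}

# --------------------------------------------------------------------------
# GLCM
# --------------------------------------------------------------------------

# Features of one normalised symmetric co-occurrence matrix p over the grey
# level values gvals (Ng = number of grey levels present in the ROI).
.glcmFromP <- function(p, gvals, Ng) {
  G <- length(gvals)
  i <- matrix(gvals, G, G)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  ux <- sum(gvals * px); uy <- sum(gvals * py)
  sx <- sqrt(sum(px * (gvals - ux)^2)); sy <- sqrt(sum(py * (gvals - uy)^2))

  dk <- abs(i - j)
  kd <- sort(unique(as.vector(dk)))
  pd <- vapply(kd, function(k) sum(p[dk == k]), numeric(1L))
  ks <- i + j
  kss <- sort(unique(as.vector(ks)))
  ps <- vapply(kss, function(k) sum(p[ks == k]), numeric(1L))

  da <- sum(kd * pd)
  hx <- -sum(px[px > 0] * log2(px[px > 0] + .EPS))
  hy <- -sum(py[py > 0] * log2(py[py > 0] + .EPS))
  hxy <- -sum(p[p > 0] * log2(p[p > 0] + .EPS))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p[p > 0] * log2(pxpy[p > 0] + .EPS))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0] + .EPS))

  corr <- if (sx * sy > 0) (sum(p * i * j) - ux * uy) / (sx * sy) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  mcc <- if (G > 1L) {
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)); MCC is the square root of
    # its second-largest eigenvalue
    Q <- (p / (px + .EPS)) %*% (t(p) / matrix(py + .EPS, G, G))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2L], 0))
  } else 1

  c(glcm.Autocorrelation = sum(p * i * j),
    glcm.ClusterProminence = sum(p * (i + j - ux - uy)^4),
    glcm.ClusterShade = sum(p * (i + j - ux - uy)^3),
    glcm.ClusterTendency = sum(p * (i + j - ux - uy)^2),
    glcm.Contrast = sum(p * (i - j)^2),
    glcm.Correlation = corr,
    glcm.DifferenceAverage = da,
    glcm.DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0] + .EPS)),
    glcm.DifferenceVariance = sum(pd * (kd - da)^2),
    glcm.Id = sum(pd / (1 + kd)),
    glcm.Idm = sum(pd / (1 + kd^2)),
    glcm.Idmn = sum(pd / (1 + kd^2 / Ng^2)),
    glcm.Idn = sum(pd / (1 + kd / Ng)),
    glcm.Imc1 = imc1,
    glcm.Imc2 = imc2,
    glcm.InverseVariance = sum(pd[kd > 0] / kd[kd > 0]^2),
    glcm.JointAverage = ux,
    glcm.JointEnergy = sum(p^2),
    glcm.JointEntropy = hxy,
    glcm.MCC = mcc,
    glcm.MaximumProbability = max(p),
    glcm.SumAverage = sum(kss * ps),
    glcm.SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0] + .EPS)),
    glcm.SumSquares = sum(p * (i - ux)^2))
}

#' Grey-level co-occurrence matrix features
#'
#' Symmetric co-occurrence at distance 1 over the 13 unique 3D directions;
#' each direction's matrix is normalised and its 24 features computed, then
#' averaged over directions with at least one voxel pair. Degenerate
#' single-level regions report Correlation and MCC of 1.
#'
#' @param levels integer 3D array of discretised grey levels, NA outside the
#'   mask.
#' @return named numeric vector of 24 features, keys \code{glcm.*}.
#' @export
glcmFeatures <- function(levels) {
  st <- .paddedLevels(levels)
  gvals <- sort(unique(st$lv))
  G <- length(gvals)
  rowOf <- integer(max(gvals)); rowOf[gvals] <- seq_len(G)
  ia <- rowOf[st$lv]
  feats <- NULL
  for (d in seq_len(nrow(st$dirs))) {
    nb <- st$pv[st$idx + .dirOffset(st, d)]
    ok <- !is.na(nb)
    if (!any(ok)) next
    cnt <- matrix(tabulate((rowOf[nb[ok]] - 1L) * G + ia[ok], G * G), G, G)
    cnt <- cnt + t(cnt)
    f <- .glcmFromP(cnt / sum(cnt), gvals, G)
    feats <- rbind(feats, f)
  }
  if (is.null(feats)) stop("no co-occurring voxel pairs in any direction")
  colMeans(feats)
}

# --------------------------------------------------------------------------
# GLRLM
# --------------------------------------------------------------------------

.glrlmFromCounts <- function(P, gvals, Np) {
  Nz <- sum(P)
  jj <- seq_len(ncol(P))
  i2 <- gvals^2
  j2 <- jj^2
  ri <- rowSums(P)   # per grey level
  rj <- colSums(P)   # per run length
  p <- P / Nz
  mu_i <- sum(rowSums(p) * gvals)
  mu_j <- sum(colSums(p) * jj)
  c(glrlm.GreyLevelNonUniformity = sum(ri^2) / Nz,
    glrlm.GreyLevelNonUniformityNormalized = sum(ri^2) / Nz^2,
    glrlm.GreyLevelVariance = sum(rowSums(p) * (gvals - mu_i)^2),
    glrlm.HighGreyLevelRunEmphasis = sum(ri * i2) / Nz,
    glrlm.LongRunEmphasis = sum(rj * j2) / Nz,
    glrlm.LongRunHighGreyLevelEmphasis = sum(P * outer(i2, j2)) / Nz,
    glrlm.LongRunLowGreyLevelEmphasis = sum(P * outer(1 / i2, j2)) / Nz,
    glrlm.LowGreyLevelRunEmphasis = sum(ri / i2) / Nz,
    glrlm.RunEntropy = -sum(p[p > 0] * log2(p[p > 0] + .EPS)),
    glrlm.RunLengthNonUniformity = sum(rj^2) / Nz,
    glrlm.RunLengthNonUniformityNormalized = sum(rj^2) / Nz^2,
    glrlm.RunPercentage = Nz / Np,
    glrlm.RunVariance = sum(colSums(p) * (jj - mu_j)^2),
    glrlm.ShortRunEmphasis = sum(rj / j2) / Nz,
    glrlm.ShortRunHighGreyLevelEmphasis = sum(P * outer(i2, 1 / j2)) / Nz,
    glrlm.ShortRunLowGreyLevelEmphasis = sum(P * outer(1 / i2, 1 / j2)) / Nz)
}

#' Grey-level run-length matrix features
#'
#' Runs of consecutive equal grey levels along each of the 13 unique 3D
#' directions (distance 1); out-of-mask voxels break runs. The 16 features
#' are computed per direction and averaged.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 16 features, keys \code{glrlm.*}.
#' @export
glrlmFeatures <- function(levels) {
  dims <- dim(levels)
  idx <- which(!is.na(levels))
  gvals <- sort(unique(levels[idx]))
  G <- length(gvals)
  rowOf <- integer(max(gvals)); rowOf[gvals] <- seq_len(G)
  xyz <- coordsOfIndex(idx, dims)
  lv <- rowOf[levels[idx]]
  Np <- length(idx)
  dirs <- uniqueDirections13()
  feats <- NULL
  for (d in seq_len(nrow(dirs))) {
    dx <- dirs[d, 1L]; dy <- dirs[d, 2L]; dz <- dirs[d, 3L]
    s <- dx^2 + dy^2 + dz^2
    t <- dx * xyz[, 1L] + dy * xyz[, 2L] + dz * xyz[, 3L]
    # cross product with the direction identifies the lattice line
    k1 <- dy * xyz[, 3L] - dz * xyz[, 2L]
    k2 <- dz * xyz[, 1L] - dx * xyz[, 3L]
    k3 <- dx * xyz[, 2L] - dy * xyz[, 1L]
    ord <- order(k1, k2, k3, t)
    newRun <- c(TRUE, diff(k1[ord]) != 0 | diff(k2[ord]) != 0 |
                  diff(k3[ord]) != 0 | diff(t[ord]) != s |
                  diff(lv[ord]) != 0)
    runId <- cumsum(newRun)
    runLen <- tabulate(runId)
    runLev <- lv[ord][newRun]
    maxLen <- max(runLen)
    P <- matrix(tabulate((runLen - 1L) * G + runLev, G * maxLen), G, maxLen)
    feats <- rbind(feats, .glrlmFromCounts(P, gvals, Np))
  }
  colMeans(feats)
}

# --------------------------------------------------------------------------
# GLSZM
# --------------------------------------------------------------------------

#' Grey-level size-zone matrix features
#'
#' Zones are 26-connected components of equal grey level within the mask;
#' a single matrix of (grey level, zone size) counts yields the 16 features.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 16 features, keys \code{glszm.*}.
#' @export
glszmFeatures <- function(levels) {
  idx <- which(!is.na(levels))
  gvals <- sort(unique(levels[idx]))
  G <- length(gvals)
  Np <- length(idx)
  sizes <- list()
  for (g in seq_along(gvals)) {
    m <- !is.na(levels) & levels == gvals[g]
    lab <- labelComponents(m, 26L)
    sizes[[g]] <- tabulate(lab[lab > 0L])
  }
  maxSize <- max(unlist(sizes))
  P <- matrix(0, G, maxSize)
  for (g in seq_along(gvals)) {
    tb <- tabulate(sizes[[g]], maxSize)
    P[g, ] <- tb
  }
  Nz <- sum(P)
  jj <- seq_len(maxSize)
  i2 <- gvals^2; j2 <- jj^2
  ri <- rowSums(P); rj <- colSums(P)
  p <- P / Nz
  mu_i <- sum(rowSums(p) * gvals)
  mu_j <- sum(colSums(p) * jj)
  c(glszm.GreyLevelNonUniformity = sum(ri^2) / Nz,
    glszm.GreyLevelNonUniformityNormalized = sum(ri^2) / Nz^2,
    glszm.GreyLevelVariance = sum(rowSums(p) * (gvals - mu_i)^2),
    glszm.HighGreyLevelZoneEmphasis = sum(ri * i2) / Nz,
    glszm.LargeAreaEmphasis = sum(rj * j2) / Nz,
    glszm.LargeAreaHighGreyLevelEmphasis = sum(P * outer(i2, j2)) / Nz,
    glszm.LargeAreaLowGreyLevelEmphasis = sum(P * outer(1 / i2, j2)) / Nz,
    glszm.LowGreyLevelZoneEmphasis = sum(ri / i2) / Nz,
    glszm.SizeZoneNonUniformity = sum(rj^2) / Nz,
    glszm.SizeZoneNonUniformityNormalized = sum(rj^2) / Nz^2,
    glszm.SmallAreaEmphasis = sum(rj / j2) / Nz,
    glszm.SmallAreaHighGreyLevelEmphasis = sum(P * outer(i2, 1 / j2)) / Nz,
    glszm.SmallAreaLowGreyLevelEmphasis = sum(P * outer(1 / i2, 1 / j2)) / Nz,
    glszm.ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0] + .EPS)),
    glszm.ZonePercentage = Nz / Np,
    glszm.ZoneVariance = sum(colSums(p) * (jj - mu_j)^2))
}

# --------------------------------------------------------------------------
# GLDM
# --------------------------------------------------------------------------

#' Grey-level dependence matrix features
#'
#' A neighbour at Chebyshev distance 1 (26-neighbourhood) is dependent on the
#' centre voxel when their grey levels are equal (alpha = 0). The matrix
#' counts (grey level, number of dependent neighbours + 1); its 14 features
#' follow the standard definitions.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 14 features, keys \code{gldm.*}.
#' @export
gldmFeatures <- function(levels) {
  st <- .paddedLevels(levels)
  gvals <- sort(unique(st$lv))
  G <- length(gvals)
  rowOf <- integer(max(gvals)); rowOf[gvals] <- seq_len(G)
  dep <- integer(length(st$idx))
  for (loff in st$offs) {
    nb <- st$pv[st$idx + loff]
    dep <- dep + (!is.na(nb) & nb == st$lv)
  }
  jv <- dep + 1L                           # dependence column (>= 1)
  iv <- rowOf[st$lv]
  Nd <- max(jv)
  P <- matrix(tabulate((jv - 1L) * G + iv, G * Nd), G, Nd)
  Nz <- sum(P)                             # every masked voxel contributes
  jj <- seq_len(Nd)
  i2 <- gvals^2; j2 <- jj^2
  ri <- rowSums(P); rj <- colSums(P)
  p <- P / Nz
  mu_i <- sum(rowSums(p) * gvals)
  mu_j <- sum(colSums(p) * jj)
  c(gldm.DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0] + .EPS)),
    gldm.DependenceNonUniformity = sum(rj^2) / Nz,
    gldm.DependenceNonUniformityNormalized = sum(rj^2) / Nz^2,
    gldm.DependenceVariance = sum(colSums(p) * (jj - mu_j)^2),
    gldm.GreyLevelNonUniformity = sum(ri^2) / Nz,
    gldm.GreyLevelVariance = sum(rowSums(p) * (gvals - mu_i)^2),
    gldm.HighGreyLevelEmphasis = sum(ri * i2) / Nz,
    gldm.LargeDependenceEmphasis = sum(rj * j2) / Nz,
    gldm.LargeDependenceHighGreyLevelEmphasis = sum(P * outer(i2, j2)) / Nz,
    gldm.LargeDependenceLowGreyLevelEmphasis = sum(P * outer(1 / i2, j2)) / Nz,
    gldm.LowGreyLevelEmphasis = sum(ri / i2) / Nz,
    gldm.SmallDependenceEmphasis = sum(rj / j2) / Nz,
    gldm.SmallDependenceHighGreyLevelEmphasis = sum(P * outer(i2, 1 / j2)) / Nz,
    gldm.SmallDependenceLowGreyLevelEmphasis = sum(P * outer(1 / i2, 1 / j2)) / Nz)
}

# --------------------------------------------------------------------------
# NGTDM
# --------------------------------------------------------------------------

#' Neighbourhood grey-tone difference matrix features
#'
#' For every masked voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its grey level and the mean level of those
#' neighbours is accumulated per grey level; the 5 features follow the
#' standard definitions (Coarseness capped at 1e6 for a zero denominator).
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 5 features, keys \code{ngtdm.*}.
#' @export
ngtdmFeatures <- function(levels) {
  st <- .paddedLevels(levels)
  nbSum <- numeric(length(st$idx))
  nbCnt <- integer(length(st$idx))
  for (loff in st$offs) {
    nb <- st$pv[st$idx + loff]
    fin <- !is.na(nb)
    nbSum <- nbSum + ifelse(fin, nb, 0L)
    nbCnt <- nbCnt + fin
  }
  use <- nbCnt > 0L
  lv <- st$lv[use]
  Abar <- nbSum[use] / nbCnt[use]
  gvals <- sort(unique(lv))
  Ngp <- length(gvals)
  Nvp <- length(lv)
  si <- vapply(gvals, function(g) sum(abs(g - Abar[lv == g])), numeric(1L))
  ni <- vapply(gvals, function(g) sum(lv == g), numeric(1L))
  pi_ <- ni / Nvp

  iMat <- outer(gvals, gvals, `-`)
  pOut <- outer(pi_, pi_)
  coarse <- sum(pi_ * si)
  coarseness <- if (coarse > 0) 1 / coarse else 1e6
  contrast <- if (Ngp > 1L)
    sum(pOut * iMat^2) / (Ngp * (Ngp - 1)) * sum(si) / Nvp else 0
  busy <- sum(abs(outer(gvals * pi_, gvals * pi_, `-`)))
  busyness <- if (Ngp > 1L && busy > 0) sum(pi_ * si) / busy else 0
  psum <- outer(pi_, pi_, `+`)
  pssum <- outer(pi_ * si, pi_ * si, `+`)
  complexity <- sum(abs(iMat) * pssum / psum) / Nvp
  strength <- if (sum(si) > 0) sum(psum * iMat^2) / sum(si) else 0
  c(ngtdm.Busyness = busyness,
    ngtdm.Coarseness = coarseness,
    ngtdm.Complexity = complexity,
    ngtdm.Contrast = contrast,
    ngtdm.Strength = strength)
}
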