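#' @importFrom stats quantile rnorm runif sd var cor
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a hash of a character string; returns a non-negative integer
# < 2^31 so it can seed R's RNG directly.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # overflow-safe multiply by the FNV prime 16777619 = 2^24 + 403 mod 2^32
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  h %% 2147483647
}

# Derive a reproducible sub-seed from a master seed and a stream label, so
# that independent stages (labels, geometry, kinetics, noise) can be re-run
# in isolation without consuming each other's random numbers.
deriveSeed <- function(seed, ...) {
  fnv1a32(paste(c(format(seed), vapply(list(...), format, "")), collapse = "/"))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Linear index <-> (x, y, z) coordinate helpers for 3D arrays.
coordsOfIndex <- function(idx, dims) {
  idx0 <- idx - 1L
  x <- idx0 %% dims[1L]
  y <- (idx0 %/% dims[1L]) %% dims[2L]
  z <- idx0 %/% (dims[1L] * dims[2L])
  cbind(x + 1L, y + 1L, z + 1L)
}

indexOfCoords <- function(xyz, dims) {
  (xyz[, 1L] - 1L) + dims[1L] * ((xyz[, 2L] - 1L) + dims[2L] * (xyz[, 3L] - 1L)) + 1L
}

# The 26-neighbourhood offsets (and the 13 unique half-space directions used
# for co-occurrence and run-length scanning).
neighbourOffsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

uniqueDirections13 <- function() {
  g <- neighbourOffsets26()
  keep <- g[, 3L] > 0L | (g[, 3L] == 0L & (g[, 2L] > 0L | (g[, 2L] == 0L & g[, 1L] > 0L)))
  g[keep, , drop = FALSE]
}

# Zero-pad a 3D array by one voxel on every face (fill = padding value).
padArray <- function(arr, fill) {
  dims <- dim(arr)
  out <- array(fill, dims + 2L)
  out[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)] <- arr
  out
}

# Linear-index offsets of the 26- (or 6-) neighbourhood in a padded array.
paddedOffsets <- function(pdims, connectivity = 26L) {
  offs <- neighbourOffsets26()
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  offs[, 1L] + pdims[1L] * (offs[, 2L] + pdims[2L] * offs[, 3L])
}

# Label the connected components of a logical 3D array (26-connectivity by
# default). Returns an integer array of the same shape, 0 outside.
labelComponents <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  pm <- padArray(mask, FALSE)
  pdims <- dims + 2L
  loffs <- paddedOffsets(pdims, connectivity)
  labels <- array(0L, pdims)
  idx <- which(pm)
  lab <- 0L
  for (seedIdx in idx) {
    if (labels[seedIdx] != 0L) next
    lab <- lab + 1L
    labels[seedIdx] <- lab
    queue <- seedIdx
    while (length(queue)) {
      nb <- unique(as.vector(outer(queue, loffs, `+`)))
      nb <- nb[pm[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      queue <- nb
    }
  }
  labels[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L), drop = FALSE]
}
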