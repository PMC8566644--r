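# Seeded random small-image fixtures shared by the radiomics tests and the
# cross-implementation oracle check. All fixtures are isotropic at the
# 2.03-mm analysis grid so the oracle sees exactly the discretised volume.

makeRadiomicsFixture <- function(seed) {
  withSeed(seed, {
    dims <- sample(8:13, 3L, replace = TRUE)
    ttpLike <- runif(1) < 0.2
    x <- slice.index(array(0, dims), 1L)
    y <- slice.index(array(0, dims), 2L)
    z <- slice.index(array(0, dims), 3L)
    img <- array(runif(prod(dims)), dims)
    for (b in 1:3) {
      ctr <- runif(3, 0.2, 0.8) * dims
      sig <- runif(1, 1.5, 4)
      amp <- runif(1, 1, 3)
      img <- img + amp * exp(-((x - ctr[1L])^2 + (y - ctr[2L])^2 +
                                 (z - ctr[3L])^2) / (2 * sig^2))
    }
    ctr <- dims / 2 + runif(3, -1, 1)
    semi <- pmax(dims / 2 - runif(3, 1.2, 2.2), 2.2)
    mask <- ((x - ctr[1L]) / semi[1L])^2 + ((y - ctr[2L]) / semi[2L])^2 +
      ((z - ctr[3L]) / semi[3L])^2 <= 1
    mask[mask] <- runif(sum(mask)) > 0.08      # irregular holes
    if (sum(mask) < 20L) mask <- ((x - ctr[1L]) / semi[1L])^2 +
        ((y - ctr[2L]) / semi[2L])^2 + ((z - ctr[3L]) / semi[3L])^2 <= 1
    if (ttpLike) {
      img <- array(sample(c(2.5, 7.5, 12.5, 17.5, 25, 35), prod(dims),
                          replace = TRUE), dims)
      bw <- 5
    } else {
      v <- img[mask]
      bw <- (max(v) - min(v)) / sample(4:8, 1L)
    }
    list(image = img, mask = mask, binWidth = bw, spacing = rep(2.03, 3L))
  })
}

# Run the numpy/scipy reference implementation on a list of fixtures;
# returns a list of named feature vectors (or NULL if python is missing).
runRadiomicsOracle <- function(fixtures) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) return(NULL)
  script <- system.file("oracle", "radiomics_oracle.py", package = "dynFET")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  # doubles as %.17g strings: exact binary round-trip through JSON
  payload <- lapply(fixtures, function(f)
    list(dims = dim(f$image), spacing = sprintf("%.17g", f$spacing),
         image = sprintf("%.17g", as.vector(f$image)),
         mask = as.integer(f$mask),
         binWidth = sprintf("%.17g", f$binWidth)))
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = FALSE)
  status <- system2(python, c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("radiomics oracle failed: ", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(fout)
  lapply(res, function(r) unlist(r))
}
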