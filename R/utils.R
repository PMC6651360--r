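# Internal helpers shared across modules.

# Half-up rounding (round() in R rounds half to even, which does not match
# the table conventions used for reporting percentages).
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Cover percent on the decile grid (half-up at the deciles).
decileCoverPct <- function(frac) {
  as.integer(10 * floor(frac * 10 + 0.5))
}

strataLevels <- c("20-40", "50-70", "80-100")

# Stratum of a decile cover percentage; exhaustive for coverPct >= 20.
stratumOf <- function(coverPct) {
  out <- rep("none", length(coverPct))
  out[coverPct >= 20 & coverPct <= 40] <- "20-40"
  out[coverPct >= 50 & coverPct <= 70] <- "50-70"
  out[coverPct >= 80] <- "80-100"
  out
}

# Decile cover values belonging to each stratum.
stratumDeciles <- function(stratum) {
  switch(stratum,
    "20-40" = c(20L, 30L, 40L),
    "50-70" = c(50L, 60L, 70L),
    "80-100" = c(80L, 90L, 100L),
    stop("unknown stratum: ", stratum)
  )
}

# North-up geotransform with origin at the top-left corner of pixel (1, 1).
defaultGeotransform <- function(rows, gsd) {
  c(0, gsd, 0, rows * gsd, 0, -gsd)
}

# Map coordinates of pixel centres.
pixelCenterXY <- function(row, col, geotransform) {
  x <- geotransform[1] + (col - 0.5) * geotransform[2]
  y <- geotransform[4] + (row - 0.5) * geotransform[6]
  cbind(x = x, y = y)
}

# Inverse: fractional (row, col) of a map coordinate.
mapToRowCol <- function(x, y, geotransform) {
  col <- (x - geotransform[1]) / geotransform[2] + 0.5
  row <- (y - geotransform[4]) / geotransform[6] + 0.5
  cbind(row = row, col = col)
}

# Dense one-dimensional Gaussian smoothing operator with renormalized,
# truncated kernels (rows sum to 1); used separably on rows and columns.
gaussianSmoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-0.5 * ((i - j) / sigma)^2))
  K[K < exp(-0.5 * 9)] <- 0  # truncate at 3 sigma
  K / rowSums(K)
}

# Seeded Dirichlet(alpha, ..., alpha) draws, n x k.
rdirichlet <- function(n, k, alpha = 1) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  g / rowSums(g)
}

# Deterministic sub-seeds derived from a master seed, kept below 2^31.
deriveSeeds <- function(masterSeed, names) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(masterSeed %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  stats::setNames(as.integer(s), names)
}

# Matrix view of a cube's valid pixels (n_valid x bands), plus the index
# of the valid pixels in column-major order.
validPixelMatrix <- function(cube) {
  d <- dim(cube@data)
  X <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  keep <- which(!as.vector(cube@nodataMask))
  list(X = X[keep, , drop = FALSE], index = keep, dim = d)
}

# Pixel (row, col) matrix -> column-major linear index.
rcToIndex <- function(px, rows) {
  (px[, 2L] - 1L) * rows + px[, 1L]
}
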