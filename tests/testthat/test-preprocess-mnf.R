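test_that("Savitzky-Golay smoothing reproduces polynomials and constants", {
  B <- 30
  idx <- seq_len(B)
  X <- rbind(rep(0.4, B),                      # constant
             0.1 + 0.01 * idx - 2e-4 * idx^2)  # exact degree-2 polynomial
  cube <- cubeFromMatrix(X, rows = 2, cols = 1)
  sm <- savitzkyGolaySmooth(cube, window = 13, polyorder = 2)
  Y <- matrix(cubeData(sm), ncol = B)
  expect_equal(Y[1, ], X[1, ], tolerance = 1e-12)
  expect_equal(Y[2, ], X[2, ], tolerance = 1e-10)
})

test_that("Savitzky-Golay matches an independent sliding least-squares fit", {
  set.seed(31)
  B <- 40
  y <- runif(B)
  cube <- cubeFromMatrix(matrix(y, 1), rows = 1, cols = 1)
  got <- as.vector(cubeData(savitzkyGolaySmooth(cube, 13, 2)))
  want <- slidingLeastSquares(y, 13L, 2L)
  expect_lt(max(abs(got - want)), 1e-10)
  # also at a different window/order
  got2 <- as.vector(cubeData(savitzkyGolaySmooth(cube, 9, 3)))
  want2 <- slidingLeastSquares(y, 9L, 3L)
  expect_lt(max(abs(got2 - want2)), 1e-10)
})

test_that("Savitzky-Golay rejects invalid windows", {
  cube <- cubeFromMatrix(matrix(runif(20), 1), 1, 1)
  expect_error(savitzkyGolaySmooth(cube, window = 12), "odd")
  expect_error(savitzkyGolaySmooth(cube, window = 3, polyorder = 3),
               "exceed")
  expect_error(savitzkyGolaySmooth(cube, window = 21), "not exceed")
})

test_that("noise covariance of a constant cube is zero", {
  cube <- cubeFromMatrix(matrix(0.5, 60, 5), rows = 6, cols = 10)
  expect_equal(estimateNoiseCovariance(cube), matrix(0, 5, 5),
               ignore_attr = TRUE)
})

test_that("shift-difference estimator recovers i.i.d. noise variance", {
  set.seed(8)
  B <- 6
  n <- 120 * 100
  sigma <- 0.05
  X <- matrix(0.4, n, B) + matrix(rnorm(n * B, 0, sigma), n, B)
  cube <- cubeFromMatrix(X, rows = 120, cols = 100)
  N <- estimateNoiseCovariance(cube)
  expect_true(all(abs(diag(N) - sigma^2) < 0.1 * sigma^2))
  # symmetric PSD
  expect_equal(N, t(N))
  expect_gte(min(eigen(N, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("shift differences beat the raw covariance as a noise estimate", {
  set.seed(9)
  rows <- 60; cols <- 80; B <- 5
  sigma <- 0.02
  # smooth signal: low-frequency spatial gradients per band
  r <- row(matrix(0, rows, cols)) / rows
  co <- col(matrix(0, rows, cols)) / cols
  X <- sapply(1:B, function(b) as.vector(0.3 + 0.1 * sin(2 * pi * (r + b * co))))
  noise <- matrix(rnorm(rows * cols * B, 0, sigma), ncol = B)
  cube <- cubeFromMatrix(X + noise, rows, cols)
  trueN <- diag(rep(sigma^2, B))
  est <- estimateNoiseCovariance(cube)
  raw <- cov(X + noise)
  frob <- function(M) sqrt(sum(M^2))
  expect_lt(frob(est - trueN), frob(raw - trueN))
})

test_that("MNF matches a dense generalized eigensolver on a small cube", {
  set.seed(10)
  B <- 5
  X <- matrix(rnorm(100 * B, 0.5, 0.1), 100, B)
  X[, 2] <- X[, 1] * 0.5 + X[, 2] * 0.3  # induce correlation
  cube <- cubeFromMatrix(X, rows = 10, cols = 10)
  A <- rWishart(1, B + 2, diag(B) * 1e-3)[, , 1]
  N <- (A + t(A)) / 2
  res <- mnfTransform(cube, N)
  # oracle: plain (nonsymmetric) eigensolve of solve(N) %*% total
  ev <- sort(Re(eigen(solve(N) %*% cov(X))$values), decreasing = TRUE)
  expect_lt(max(abs(eigenvalues(res) - ev)), 1e-8)
  # eigenvalues nonincreasing, noise whitened, components uncorrelated
  expect_true(all(diff(eigenvalues(res)) <= 1e-10))
  V <- res@forwardTransform
  expect_lt(max(abs(t(V) %*% N %*% V - diag(B))), 1e-6)
  Y <- matrix(cubeData(res@components), ncol = B)
  C <- cov(Y)
  expect_lt(max(abs(C[upper.tri(C)])) / max(diag(C)), 1e-6)
})

test_that("MNF with identity noise reduces to PCA", {
  set.seed(12)
  B <- 6
  X <- matrix(rnorm(400 * B), 400, B) %*% matrix(rnorm(B * B), B)
  cube <- cubeFromMatrix(X, rows = 20, cols = 20)
  res <- mnfTransform(cube, diag(B))
  pca <- eigen(cov(X), symmetric = TRUE)
  expect_equal(eigenvalues(res), pca$values, tolerance = 1e-8)
  for (j in 1:B) {
    # loadings equal up to sign
    expect_equal(abs(sum(res@forwardTransform[, j] * pca$vectors[, j])),
                 1, tolerance = 1e-6)
  }
})

test_that("component selection keeps k bands and k = B is lossless", {
  set.seed(13)
  B <- 8
  X <- matrix(rnorm(250 * B, 0.4, 0.05), 250, B)
  cube <- cubeFromMatrix(X, rows = 25, cols = 10)
  res <- mnfTransform(cube, diag(B) * 1e-4)
  expect_equal(nBands(selectComponents(res, 3)), 3)
  expect_error(selectComponents(res, 0), "between")
  expect_error(selectComponents(res, B + 1), "between")
  back <- mnfBackTransform(res)
  expect_lt(max(abs(cubeData(back) - cubeData(cube))), 1e-8)
})

test_that("nodata pixels are excluded and propagated", {
  set.seed(14)
  B <- 4
  X <- matrix(rnorm(100 * B, 0.5, 0.05), 100, B)
  cube <- cubeFromMatrix(X, rows = 10, cols = 10)
  cube@nodataMask[1:3, 1] <- TRUE
  res <- mnfTransform(cube, diag(B) * 1e-4)
  comp <- cubeData(res@components)
  expect_true(all(is.na(comp[1:3, 1, ])))
  expect_true(all(is.finite(comp[4:10, , ])))
})
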