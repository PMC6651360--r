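#' Savitzky-Golay smoothing operator
#'
#' Builds the bands x bands linear operator whose row b holds the weights
#' of the local least-squares polynomial fit evaluated at band b. Interior
#' rows carry the classic Savitzky-Golay coefficients; near the spectrum
#' edges the window is truncated to the available bands and the
#' polynomial is fitted on the truncated window.
#'
#' @param bands Number of spectral bands.
#' @param window Odd window length (bands), default 13.
#' @param polyorder Polynomial degree, default 2.
#' @return A bands x bands matrix \code{S} such that smoothed spectra are
#'   \code{spectra \%*\% t(S)} (spectra in rows).
#' @export
sgSmoothingMatrix <- function(bands, window = 13L, polyorder = 2L) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > bands) stop("window must not exceed the number of bands")
  h <- (window - 1L) %/% 2L
  S <- matrix(0, bands, bands)
  for (b in seq_len(bands)) {
    lo <- max(1L, b - h)
    hi <- min(bands, b + h)
    off <- (lo:hi) - b
    X <- outer(off, 0:polyorder, `^`)
    # evaluation at offset 0 = first row of the hat projector
    w <- c(1, rep(0, polyorder)) %*% solve(crossprod(X), t(X))
    S[b, lo:hi] <- w
  }
  S
}

#' Smooth each pixel spectrum with a Savitzky-Golay filter
#'
#' Replaces every pixel's spectrum by the value of a local least-squares
#' polynomial (default: 13-band window, degree 2), the standard
#' reflectance-smoothing step before the MNF transform.
#'
#' @param cube A \linkS4class{HyperCube}.
#' @param window Odd window length in bands.
#' @param polyorder Polynomial degree.
#' @return A smoothed \linkS4class{HyperCube}.
#' @export
savitzkyGolaySmooth <- function(cube, window = 13L, polyorder = 2L) {
  stopifnot(is(cube, "HyperCube"))
  S <- sgSmoothingMatrix(nBands(cube), window, polyorder)
  d <- dim(cube@data)
  X <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  out <- cube
  out@data <- array(X %*% t(S), dim = d)
  out
}

#' Estimate the band noise covariance by horizontal shift differences
#'
#' Differences each valid pixel's spectrum against its right neighbour
#' and returns \code{cov(differences) / 2}. Because spatially smooth
#' signal largely cancels in neighbour differences while i.i.d. noise
#' adds (doubling its variance), this is the standard MNF noise model
#' when no dark-current measurement is available.
#'
#' @param cube A \linkS4class{HyperCube} with at least two valid columns.
#' @return Symmetric positive semidefinite bands x bands matrix.
#' @export
estimateNoiseCovariance <- function(cube) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  if (d[2] < 2L) stop("need at least 2 columns of pixels")
  X <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  valid <- !cube@nodataMask
  left <- which(valid[, -d[2], drop = FALSE])
  # linear index of a pixel and its right neighbour (column-major)
  leftIdx <- ((left - 1L) %/% d[1]) * d[1] + ((left - 1L) %% d[1]) + 1L
  rightIdx <- leftIdx + d[1]
  keep <- !as.vector(cube@nodataMask)[rightIdx]
  leftIdx <- leftIdx[keep]
  rightIdx <- rightIdx[keep]
  if (length(leftIdx) < d[3] + 1L)
    warning("fewer difference samples than bands + 1; ",
            "noise covariance estimate is ill-conditioned")
  D <- X[leftIdx, , drop = FALSE] - X[rightIdx, , drop = FALSE]
  N <- stats::cov(D) / 2
  (N + t(N)) / 2
}

#' Minimum Noise Fraction transform
#'
#' Solves the generalized symmetric eigenproblem
#' \eqn{\Sigma_{total} v = \lambda \Sigma_{noise} v} by noise whitening
#' (Cholesky) followed by an eigendecomposition of the whitened total
#' covariance, and projects the mean-centred pixels onto the
#' eigenvectors. Components are ordered by decreasing eigenvalue, i.e.
#' by decreasing signal-to-noise ratio, and each eigenvector is scaled so
#' its largest-magnitude loading is positive (a reproducible sign
#' convention). In the transformed space the noise covariance maps to the
#' identity. If the supplied noise covariance is not positive definite it
#' is regularized by adding \code{1e-8 * trace / bands} to the diagonal.
#'
#' @param cube A \linkS4class{HyperCube} (typically smoothed reflectance).
#' @param noiseCov Bands x bands noise covariance; estimated with
#'   \code{\link{estimateNoiseCovariance}} when omitted.
#' @return An \linkS4class{MNFResult}.
#' @export
mnfTransform <- function(cube, noiseCov = NULL) {
  stopifnot(is(cube, "HyperCube"))
  if (is.null(noiseCov)) noiseCov <- estimateNoiseCovariance(cube)
  B <- nBands(cube)
  if (!identical(dim(noiseCov), c(B, B)))
    stop("noiseCov must be bands x bands")
  vp <- validPixelMatrix(cube)
  mu <- colMeans(vp$X)
  Xc <- sweep(vp$X, 2, mu)
  sigmaTotal <- stats::cov(vp$X)

  N <- (noiseCov + t(noiseCov)) / 2
  eps <- 1e-8 * sum(diag(N)) / B
  if (eps == 0) eps <- 1e-12
  U <- tryCatch(chol(N), error = function(e) NULL)
  if (is.null(U)) U <- tryCatch(chol(N + eps * diag(B)), error = function(e) NULL)
  if (is.null(U))
    stop("noise covariance is singular even after regularization")
  Wi <- backsolve(U, diag(B))            # inverse of the Cholesky factor
  A <- t(Wi) %*% sigmaTotal %*% Wi
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  V <- Wi %*% e$vectors                  # columns: generalized eigenvectors
  for (j in seq_len(B)) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) V[, j] <- -V[, j]
  }
  Y <- Xc %*% V
  d <- vp$dim
  comp <- array(NA_real_, dim = c(d[1] * d[2], B))
  comp[vp$index, ] <- Y
  compCube <- new("HyperCube",
                  data = array(comp, dim = d),
                  wavelengths = as.numeric(seq_len(B)),
                  gsd = cube@gsd,
                  geotransform = cube@geotransform,
                  nodataMask = cube@nodataMask)
  new("MNFResult",
      forwardTransform = V,
      eigenvalues = e$values,
      components = compCube,
      noiseCov = N,
      signalCov = sigmaTotal,
      center = mu)
}

#' Select the leading MNF components
#'
#' Returns the first \code{k} (most informative, highest-SNR) components
#' as a k-band cube; the eigenvalue sequence is attached as attribute
#' \code{"eigenvalues"} for eigenvalue-plot inspection.
#'
#' @param result An \linkS4class{MNFResult}.
#' @param k Number of components to keep (default 30).
#' @return A k-band \linkS4class{HyperCube}.
#' @export
selectComponents <- function(result, k = 30L) {
  stopifnot(is(result, "MNFResult"))
  B <- length(result@eigenvalues)
  if (k < 1L || k > B)
    stop("k must be between 1 and the number of bands (", B, ")")
  cube <- result@components
  cube@data <- cube@data[, , seq_len(k), drop = FALSE]
  cube@wavelengths <- cube@wavelengths[seq_len(k)]
  attr(cube@data, "eigenvalues") <- result@eigenvalues
  cube
}

#' Reconstruct centred data from MNF components
#'
#' With all components kept the MNF transform is invertible; this is
#' mainly a numerical check.
#'
#' @param result An \linkS4class{MNFResult}.
#' @return A \linkS4class{HyperCube} of reconstructed (uncentred) data.
#' @export
mnfBackTransform <- function(result) {
  stopifnot(is(result, "MNFResult"))
  vp <- validPixelMatrix(result@components)
  Xc <- vp$X %*% solve(result@forwardTransform)
  X <- sweep(Xc, 2, result@center, `+`)
  d <- vp$dim
  out <- array(NA_real_, dim = c(d[1] * d[2], d[3]))
  out[vp$index, ] <- X
  cube <- result@components
  cube@data <- array(out, dim = d)
  cube
}
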