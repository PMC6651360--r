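#' Default wavelength grid
#'
#' Evenly spaced band centres spanning the VNIR-SWIR range 400-2500 nm.
#' The full-scale default of 430 bands matches the channel count of a
#' combined VNIR/SWIR airborne imaging-spectrometer cube at 1 m GSD;
#' reduced grids (e.g. 60 bands) keep the same spectral envelope for fast
#' experiments.
#'
#' @param bands Number of bands.
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @export
defaultWavelengths <- function(bands = 430L) {
  if (bands < 2L) stop("need at least 2 bands")
  seq(400, 2500, length.out = bands)
}

# Smooth vegetation-like reflectance curve from shape parameters:
# visible baseline, green peak (~550 nm), chlorophyll trough (~680 nm),
# logistic red edge to a NIR plateau, gentle SWIR decline, and water
# absorption dips near 1450 and 1940 nm.
vegetationCurve <- function(wl, p) {
  vis <- p$vis + p$green * exp(-0.5 * ((wl - 550) / 35)^2) -
    p$trough * exp(-0.5 * ((wl - 680) / 28)^2)
  edge <- 1 / (1 + exp(-(wl - p$redEdgePos) / p$redEdgeWidth))
  swirDecline <- 1 - p$slope * pmax(0, wl - 1300) / 1200
  nir <- p$nir * edge * swirDecline
  dips <- p$d1 * exp(-0.5 * ((wl - 1450) / 45)^2) +
    p$d2 * exp(-0.5 * ((wl - 1940) / 60)^2)
  r <- vis + nir - dips * edge
  pmin(pmax(r, 0), 1)
}

#' Generate a synthetic vegetation endmember spectrum
#'
#' Builds a smooth vegetation-like reflectance curve (green peak near
#' 550 nm, chlorophyll trough near 680 nm, red-edge rise to a NIR
#' plateau, water-absorption dips near 1450 and 1940 nm) with
#' seed-controlled parameter jitter. Target endmembers receive a
#' systematic parameter shift, scaled by \code{separability}, so that the
#' spectral distance between the target species and the background flora
#' is tunable.
#'
#' @param kind "target" or "background".
#' @param jitterSeed Integer seed controlling the parameter jitter.
#' @param wavelengths Wavelength grid in nm (strictly increasing).
#' @param separability Scale of the systematic target-background
#'   parameter shift (1 = default scenario).
#' @return Numeric reflectance spectrum in \code{[0, 1]}, one value per
#'   wavelength.
#' @examples
#' wl <- defaultWavelengths(60)
#' s <- makeEndmember("target", jitterSeed = 1, wavelengths = wl)
#' s[which.min(abs(wl - 550))] > s[which.min(abs(wl - 680))]
#' @export
makeEndmember <- function(kind = c("target", "background"), jitterSeed = 1L,
                          wavelengths = defaultWavelengths(),
                          separability = 1) {
  kind <- match.arg(kind)
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(jitterSeed))
  p <- list(
    vis = 0.04 + stats::rnorm(1, 0, 0.005),
    green = 0.07 + stats::rnorm(1, 0, 0.015),
    trough = 0.015 + stats::rnorm(1, 0, 0.004),
    redEdgePos = 715 + stats::rnorm(1, 0, 5),
    redEdgeWidth = 11 + stats::rnorm(1, 0, 1),
    nir = 0.42 + stats::rnorm(1, 0, 0.05),
    slope = 0.45 + stats::rnorm(1, 0, 0.08),
    d1 = 0.10 + stats::rnorm(1, 0, 0.02),
    d2 = 0.14 + stats::rnorm(1, 0, 0.03)
  )
  if (kind == "target") {
    p$nir <- p$nir + 0.10 * separability
    p$redEdgePos <- p$redEdgePos + 6 * separability
    p$green <- p$green + 0.02 * separability
    p$d2 <- max(0, p$d2 - 0.04 * separability)
  }
  p$green <- max(p$green, 0.03)
  p$trough <- max(p$trough, 0.008)
  p$nir <- min(max(p$nir, 0.25), 0.9)
  vegetationCurve(wavelengths, p)
}

#' Assemble a spectral library of one target and several backgrounds
#'
#' @param nBackground Number of background endmembers.
#' @param seed Integer seed; endmember jitter seeds are derived from it.
#' @param wavelengths Wavelength grid in nm.
#' @param separability Target-background separability scale.
#' @return A \linkS4class{SpectralLibrary}.
#' @export
makeSpectralLibrary <- function(nBackground = 5L, seed = 1L,
                                wavelengths = defaultWavelengths(),
                                separability = 1) {
  seeds <- deriveSeeds(seed, c("target", paste0("bg", seq_len(nBackground))))
  spectra <- rbind(
    makeEndmember("target", seeds[1], wavelengths, separability),
    t(vapply(seq_len(nBackground), function(i) {
      makeEndmember("background", seeds[i + 1L], wavelengths, separability)
    }, numeric(length(wavelengths))))
  )
  rownames(spectra) <- c("target", paste0("background_", seq_len(nBackground)))
  new("SpectralLibrary", wavelengths = wavelengths, spectra = spectra,
      target = "target")
}

#' Spectral angle between two spectra
#'
#' Arc cosine of the normalized inner product, in radians.
#'
#' @param a,b Numeric spectra of equal length.
#' @return Angle in radians.
#' @export
spectralAngle <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

#' Simulate a spatially autocorrelated target-cover field
#'
#' White noise is smoothed with a Gaussian kernel of the given
#' correlation length and then transformed monotonically (by empirical
#' rank) into a cover fraction field such that: the fraction of pixels
#' with cover >= 0.2 equals \code{prevalenceTarget}; a fringe of low
#' cover (0-20\%) surrounds the patches; and covers within patches ramp
#' continuously from 20\% up to 100\%, so all three cover strata (20-40,
#' 50-70, 80-100\%) are populated. Background composition weights are
#' drawn per pixel from a Dirichlet distribution and spatially smoothed
#' with the same kernel, emulating a species-rich heterogeneous
#' background.
#'
#' @param rows,cols Scene size in pixels.
#' @param correlationLengthM Gaussian correlation length in metres.
#' @param prevalenceTarget Fraction of pixels with cover >= 0.2
#'   (default 0.04; the target species occupies under 5\% of the scene).
#' @param seed Integer seed.
#' @param gsd Ground sample distance in metres.
#' @param nBackground Number of background endmembers to weight.
#' @return A \linkS4class{CoverScene}.
#' @examples
#' sc <- simulateCoverField(120, 120, correlationLengthM = 8,
#'                          prevalenceTarget = 0.04, seed = 1)
#' mean(coverField(sc) >= 0.2)
#' @export
simulateCoverField <- function(rows = 500L, cols = 500L,
                               correlationLengthM = 12,
                               prevalenceTarget = 0.04, seed = 1L,
                               gsd = 1, nBackground = 5L) {
  if (prevalenceTarget < 0 || prevalenceTarget > 0.5)
    stop("prevalenceTarget must be in [0, 0.5]")
  n <- rows * cols
  set.seed(as.integer(seed))
  sigma <- correlationLengthM / gsd / 2  # kernel SD; ~2 SD per corr. length
  Kr <- gaussianSmoother(rows, sigma)
  Kc <- gaussianSmoother(cols, sigma)

  # Background composition: smoothed Dirichlet weight fields.
  W <- rdirichlet(n, nBackground)
  Warr <- array(W, dim = c(rows, cols, nBackground))
  for (k in seq_len(nBackground))
    Warr[, , k] <- Kr %*% Warr[, , k] %*% t(Kc)
  sums <- apply(Warr, c(1, 2), sum)
  for (k in seq_len(nBackground)) Warr[, , k] <- Warr[, , k] / sums

  if (prevalenceTarget == 0) {
    cover <- matrix(0, rows, cols)
  } else {
    Z <- Kr %*% matrix(stats::rnorm(n), rows, cols) %*% t(Kc)
    u <- matrix(rank(Z, ties.method = "first") / (n + 1), rows, cols)
    qhi <- 1 - prevalenceTarget
    qlo <- max(0, qhi - 1.5 * prevalenceTarget)  # low-cover fringe
    cover <- matrix(0, rows, cols)
    fringe <- u > qlo & u <= qhi
    cover[fringe] <- 0.2 * (u[fringe] - qlo) / (qhi - qlo)
    patch <- u > qhi
    # piecewise-linear rank->cover map inside patches: 35% of patch
    # pixels at sparse cover (20-45%), 25% intermediate (45-75%), 40%
    # dense (75-100%) -- expansive herbs saturate toward closed stands,
    # so dense cover is common within established patches while patch
    # margins stay sparse
    v <- (u[patch] - qhi) / (1 - qhi)
    cover[patch] <- ifelse(v <= 0.35, 0.20 + 0.25 * v / 0.35,
                    ifelse(v <= 0.60, 0.45 + 0.30 * (v - 0.35) / 0.25,
                           0.75 + 0.25 * (v - 0.60) / 0.40))
    nPatch <- sum(patch)
    inStratum <- vapply(strataLevels, function(s) {
      d <- stratumDeciles(s) / 100
      any(cover >= d[1] - 0.05 & cover < d[3] + 0.05)
    }, logical(1))
    if (nPatch < 10L || !all(inStratum))
      stop("scene too small to populate all cover strata: only ", nPatch,
           " pixels reach 20% cover (strata present: ",
           paste(strataLevels[inStratum], collapse = ", "), ")")
    got <- mean(cover >= 0.2)
    if (abs(got - prevalenceTarget) > 0.2 * prevalenceTarget)
      stop(sprintf("achieved prevalence %.4f deviates from target %.4f", got,
                   prevalenceTarget))
  }
  new("CoverScene", cover = cover, backgroundWeights = Warr, gsd = gsd,
      truthPatches = list())
}

#' Render a hyperspectral cube by linear spectral mixing
#'
#' Each pixel's spectrum is the convex combination of the target
#' endmember (weight = cover fraction) and the pixel's background
#' mixture (weight = 1 - cover), plus i.i.d. Gaussian sensor noise per
#' band, clipped to \code{[0, 1]}. Linear mixing is the structural
#' assumption that makes sub-pixel cover meaningful: at low cover the
#' pixel signature is dominated by co-occurring background plants.
#'
#' @param scene A \linkS4class{CoverScene}.
#' @param library A \linkS4class{SpectralLibrary} whose background count
#'   matches the scene's weight array.
#' @param noiseSd Additive noise standard deviation (reflectance units).
#' @param seed Integer seed for the noise.
#' @return A \linkS4class{HyperCube}.
#' @export
renderCube <- function(scene, library, noiseSd = 0.03, seed = 1L) {
  stopifnot(is(scene, "CoverScene"), is(library, "SpectralLibrary"))
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  nBg <- dim(scene@backgroundWeights)[3]
  bgRows <- setdiff(rownames(library@spectra), library@target)
  if (length(bgRows) != nBg)
    stop("library has ", length(bgRows), " background endmembers but the ",
         "scene expects ", nBg)
  d <- dim(scene@cover)
  B <- ncol(library@spectra)
  tSpec <- library@spectra[library@target, ]
  bgSpec <- library@spectra[bgRows, , drop = FALSE]
  c_ <- as.vector(scene@cover)
  W <- matrix(scene@backgroundWeights, nrow = d[1] * d[2], ncol = nBg)
  X <- c_ %o% tSpec + (1 - c_) * (W %*% bgSpec)
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    X <- X + matrix(stats::rnorm(length(X), 0, noiseSd), nrow = nrow(X))
  }
  X <- pmin(pmax(X, 0), 1)
  new("HyperCube",
      data = array(X, dim = c(d[1], d[2], B)),
      wavelengths = library@wavelengths,
      gsd = scene@gsd,
      geotransform = defaultGeotransform(d[1], scene@gsd),
      nodataMask = matrix(FALSE, d[1], d[2]))
}

# 4-connected component labelling of a logical mask via graph components.
labelComponents4 <- function(mask) {
  rows <- nrow(mask)
  cols <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = integer(0), index = idx))
  nodeId <- integer(rows * cols)
  nodeId[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% rows) + 1L
  co <- ((idx - 1L) %/% rows) + 1L
  hasR <- co < cols
  rightIdx <- idx[hasR] + rows
  keepR <- mask[rightIdx]
  eR <- cbind(nodeId[idx[hasR][keepR]], nodeId[rightIdx[keepR]])
  hasD <- r < rows
  downIdx <- idx[hasD] + 1L
  keepD <- mask[downIdx]
  eD <- cbind(nodeId[idx[hasD][keepD]], nodeId[downIdx[keepD]])
  edges <- rbind(eR, eD)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  comp <- igraph::components(g)
  list(labels = as.integer(comp$membership), index = idx)
}

#' Extract field-mappable truth patches from a cover scene
#'
#' Thresholds the cover field at \code{minCover}, labels 4-connected
#' components, and keeps those whose area (pixel count x gsd^2) reaches
#' \code{minAreaM2}. This mirrors the field-mapping rule that only
#' species patches of at least 10 m^2 with at least 20\% cover are
#' mapped as truth.
#'
#' @param scene A \linkS4class{CoverScene}.
#' @param minAreaM2 Minimum patch area in m^2.
#' @param minCover Minimum cover fraction.
#' @return List of patches; each has \code{id}, \code{pixels} (matrix of
#'   row, col), and \code{areaM2}. The empty list is returned when no
#'   patch qualifies.
#' @export
extractTruthPatches <- function(scene, minAreaM2 = 10, minCover = 0.2) {
  stopifnot(is(scene, "CoverScene"))
  mask <- scene@cover >= minCover
  lab <- labelComponents4(mask)
  if (!length(lab$index)) return(list())
  rows <- nrow(mask)
  px <- cbind(row = ((lab$index - 1L) %% rows) + 1L,
              col = ((lab$index - 1L) %/% rows) + 1L)
  out <- list()
  areaPerPixel <- scene@gsd^2
  for (k in sort(unique(lab$labels))) {
    sel <- lab$labels == k
    area <- sum(sel) * areaPerPixel
    if (area >= minAreaM2) {
      out[[length(out) + 1L]] <- list(
        id = sprintf("patch_%03d", length(out) + 1L),
        pixels = px[sel, , drop = FALSE],
        areaM2 = area
      )
    }
  }
  out
}

#' Attach truth patches to a scene
#'
#' @param scene A \linkS4class{CoverScene}.
#' @param minAreaM2,minCover Patch rules passed to
#'   \code{\link{extractTruthPatches}}.
#' @return The scene with its \code{truthPatches} slot filled.
#' @export
withTruthPatches <- function(scene, minAreaM2 = 10, minCover = 0.2) {
  scene@truthPatches <- extractTruthPatches(scene, minAreaM2, minCover)
  scene
}
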