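test_that("endmember spectra are vegetation-like, bounded and deterministic", {
  wl <- defaultWavelengths(120)
  for (seed in c(1, 5, 99)) {
    for (kind in c("target", "background")) {
      s <- makeEndmember(kind, seed, wl)
      expect_true(all(s >= 0 & s <= 1))
      expect_gt(s[which.min(abs(wl - 550))], s[which.min(abs(wl - 680))])
      expect_identical(s, makeEndmember(kind, seed, wl))
    }
  }
  expect_error(makeEndmember("target", 1, c(500, 400)), "increasing")
})

test_that("background endmembers are pairwise spectrally distinct", {
  wl <- defaultWavelengths(80)
  specs <- lapply(1:10, function(s) makeEndmember("background", s, wl))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gt(spectralAngle(specs[[i]], specs[[j]]), 0)
  }
})

test_that("spectral library has one target and valid reflectance", {
  lib <- makeSpectralLibrary(5, seed = 3, defaultWavelengths(60))
  expect_s4_class(lib, "SpectralLibrary")
  expect_equal(nrow(lib@spectra), 6)
  expect_identical(lib@target, "target")
})

test_that("cover field hits the prevalence target and populates all strata", {
  sc <- simulateCoverField(400, 400, 8, prevalenceTarget = 0.04, seed = 11)
  prev <- mean(coverField(sc) >= 0.2)
  expect_gte(prev, 0.032)
  expect_lte(prev, 0.048)
  cov <- coverField(sc)
  expect_true(any(cov >= 0.2 & cov <= 0.45))
  expect_true(any(cov >= 0.45 & cov <= 0.75))
  expect_true(any(cov >= 0.75))
  expect_true(all(cov >= 0 & cov <= 1))
  # background weights convex
  s <- apply(sc@backgroundWeights, c(1, 2), sum)
  expect_lt(max(abs(s - 1)), 1e-6)
})

test_that("cover field is deterministic and zero-prevalence yields zero", {
  a <- simulateCoverField(80, 80, 6, 0.05, seed = 2)
  b <- simulateCoverField(80, 80, 6, 0.05, seed = 2)
  expect_identical(coverField(a), coverField(b))
  z <- simulateCoverField(50, 50, 6, 0, seed = 2)
  expect_true(all(coverField(z) == 0))
})

test_that("too-small scenes fail with a diagnostic", {
  expect_error(simulateCoverField(8, 8, 4, 0.02, seed = 1), "too small")
})

test_that("rendering mixes linearly and is deterministic", {
  lib <- tinyLibrary(bands = 10, nBackground = 1)
  cover <- matrix(c(1, 0.5, 0, 0), 2, 2)
  sc <- sceneFromCover(cover, nBackground = 1)
  cube <- renderCube(sc, lib, noiseSd = 0, seed = 1)
  tSpec <- lib@spectra["target", ]
  bSpec <- lib@spectra["background_1", ]
  expect_equal(cubeData(cube)[1, 1, ], unname(tSpec), tolerance = 1e-12)
  expect_equal(cubeData(cube)[2, 1, ], unname((tSpec + bSpec) / 2),
               tolerance = 1e-12)
  expect_equal(cubeData(cube)[1, 2, ], unname(bSpec), tolerance = 1e-12)
  c2 <- renderCube(sc, lib, noiseSd = 0.01, seed = 9)
  expect_identical(cubeData(c2), cubeData(renderCube(sc, lib, 0.01, 9)))
  expect_error(renderCube(sc, lib, noiseSd = -1), "nonnegative")
})

test_that("noiseless rendering stays in the convex hull of the library", {
  lib <- makeSpectralLibrary(3, seed = 5, defaultWavelengths(25))
  sc <- simulateCoverField(40, 40, 5, 0.05, seed = 5, nBackground = 3)
  cube <- renderCube(sc, lib, noiseSd = 0, seed = 1)
  lo <- apply(lib@spectra, 2, min)
  hi <- apply(lib@spectra, 2, max)
  X <- matrix(cubeData(cube), ncol = nBands(cube))
  for (b in seq_len(nBands(cube))) {
    expect_gte(min(X[, b]), lo[b] - 1e-9)
    expect_lte(max(X[, b]), hi[b] + 1e-9)
  }
})

test_that("rendered noise magnitude matches the requested SD", {
  lib <- tinyLibrary(bands = 6, nBackground = 1)
  sc <- sceneFromCover(matrix(0.3, 120, 100), nBackground = 1)
  clean <- renderCube(sc, lib, noiseSd = 0, seed = 1)
  noisy <- renderCube(sc, lib, noiseSd = 0.01, seed = 4)
  diff <- matrix(cubeData(noisy) - cubeData(clean), ncol = 6)
  for (b in 1:6) {
    expect_gt(sd(diff[, b]), 0.008)
    expect_lt(sd(diff[, b]), 0.012)
  }
})

test_that("truth patches match the flood-fill oracle on random masks", {
  set.seed(42)
  for (rep in 1:5) {
    cover <- matrix(ifelse(runif(225) < 0.35, runif(225, 0.2, 1), 0), 15, 15)
    sc <- sceneFromCover(cover)
    patches <- extractTruthPatches(sc, minAreaM2 = 3, minCover = 0.2)
    oracle <- floodFillComponents(cover >= 0.2)
    keep <- table(oracle[oracle > 0])
    bigIds <- as.integer(names(keep)[keep >= 3])
    expect_equal(length(patches), length(bigIds))
    gotPixels <- sort(unlist(lapply(patches, function(p) {
      (p$pixels[, 2] - 1) * 15 + p$pixels[, 1]
    })))
    wantPixels <- sort(which(oracle %in% bigIds))
    expect_equal(gotPixels, wantPixels)
  }
})

test_that("truth patch area rules follow the 10 m^2 / 20% convention", {
  cover <- matrix(0, 20, 20)
  cover[3:5, 4:7] <- 1  # 3 x 4 = 12 m^2
  sc <- sceneFromCover(cover)
  patches <- extractTruthPatches(sc)
  expect_length(patches, 1)
  expect_equal(patches[[1]]$areaM2, 12)

  cover2 <- matrix(0, 20, 20)
  cover2[3:5, 4:6] <- 1  # 9 m^2, below the threshold
  expect_length(extractTruthPatches(sceneFromCover(cover2)), 0)
  expect_length(extractTruthPatches(sceneFromCover(matrix(0, 8, 8))), 0)
})
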