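# A miniature labelled world: feature cube with separable clusters and a
# hand-built design of single-pixel-list polygons.
miniWorld <- function(sep = 3, rows = 20, cols = 20, seed = 77) {
  set.seed(seed)
  B <- 4
  X <- matrix(rnorm(rows * cols * B), ncol = B)
  targetPix <- 1:60
  X[targetPix, ] <- X[targetPix, ] + sep
  cube <- cubeFromMatrix(X, rows, cols)
  toRC <- function(i) cbind(row = ((i - 1) %% rows) + 1,
                            col = ((i - 1) %/% rows) + 1)
  ids <- c(sprintf("T%02d", 1:6), sprintf("B%02d", 1:10))
  pixels <- c(
    lapply(0:5, function(k) toRC(targetPix[(k * 10 + 1):(k * 10 + 10)])),
    lapply(0:9, function(k) toRC(61 + (k * 10):(k * 10 + 9)))
  )
  names(pixels) <- ids
  meta <- data.frame(
    id = ids,
    klass = c(rep("target", 6), rep("background", 10)),
    coverPct = c(rep(100L, 6), rep(0L, 10)),
    stratum = c(rep("80-100", 6), rep("none", 10)),
    role = "unassigned",
    centerRow = 1, centerCol = 1, centerX = 0, centerY = 0,
    stringsAsFactors = FALSE
  )
  design <- new("SampleDesign", meta = meta, pixels = pixels,
                radius = 2, seed = 77L)
  list(cube = cube, design = design)
}

test_that("pixel datasets carry every member pixel with polygon labels", {
  w <- miniWorld()
  ds <- assemblePixelDataset(w$cube, w$design, c("T01", "T02", "B01"))
  expect_equal(nrow(ds@features), 30)
  expect_equal(as.vector(table(ds@labels)), c(10, 20))
  expect_equal(unique(ds@polygonId), c("T01", "T02", "B01"))
  expect_equal(ncol(ds@features), 4)
  # empty dataset refuses to train
  e <- assemblePixelDataset(w$cube, w$design, character(0))
  expect_equal(nrow(e@features), 0)
  expect_error(trainRF(e), "empty")
})

test_that("pixel counts multiply out for circle polygons", {
  sd_ <- standardSceneDesign()
  m <- polygonMeta(sd_$design)
  ids <- c(m$id[m$klass == "target"][1:30],
           m$id[m$klass == "background"][1:100])
  lib <- makeSpectralLibrary(5, 1, defaultWavelengths(12), 0.3)
  cube <- renderCube(sd_$scene, lib, 0, 1)
  ds <- assemblePixelDataset(cube, sd_$design, ids)
  expect_equal(nrow(ds@features), 30 * 13 + 100 * 13)
  expect_equal(sum(ds@labels == "target"), 390)
  expect_equal(sum(ds@labels == "background"), 1300)
})

test_that("polygon-level leakage is rejected before any fit", {
  expect_error(assertNoLeakage(c("a", "b"), c("b", "c")), "both")
  expect_true(assertNoLeakage(c("a", "b"), c("c", "d")))
})

test_that("the forest separates clear clusters and is seed-deterministic", {
  w <- miniWorld(sep = 4)
  trainIds <- c(sprintf("T%02d", 1:3), sprintf("B%02d", 1:5))
  ds <- assemblePixelDataset(w$cube, w$design, trainIds)
  model <- trainRF(ds, seed = 3)
  expect_equal(model$ntree, 100)
  # training-set accuracy on separable clusters
  pred <- predict(model, ds@features)
  expect_equal(mean(pred == ds@labels), 1.0)
  map1 <- predictMap(model, w$cube)
  model2 <- trainRF(ds, seed = 3)
  map2 <- predictMap(model2, w$cube)
  expect_identical(labelRaster(map1), labelRaster(map2))
  expect_identical(probRaster(map1), probRaster(map2))
})

test_that("single-class training data are rejected", {
  w <- miniWorld()
  ds <- assemblePixelDataset(w$cube, w$design, c("T01", "T02"))
  expect_error(trainRF(ds), "single class")
})

test_that("label-permuted training yields chance-level validation Kappa", {
  set.seed(55)
  B <- 5
  n <- 2000
  X <- matrix(rnorm(n * B), ncol = B)
  X[1:1000, ] <- X[1:1000, ] + 2
  labels <- factor(rep(c("target", "background"), each = 1000),
                   levels = c("background", "target"))
  perm <- sample(n)
  trainIdx <- perm[1:1000]
  valIdx <- perm[1001:2000]
  permLabels <- labels
  permLabels[trainIdx] <- sample(labels[trainIdx])  # break the association
  ds <- new("PixelDataset",
            features = `colnames<-`(X[trainIdx, ], paste0("comp_", 1:B)),
            labels = permLabels[trainIdx],
            polygonId = sprintf("P%04d", seq_len(1000)))
  model <- trainRF(ds, seed = 4)
  Xv <- X[valIdx, ]
  colnames(Xv) <- paste0("comp_", 1:B)
  pred <- predict(model, Xv)
  truth <- labels[valIdx]
  counts <- confusionCounts(
    tp = sum(pred == "target" & truth == "target"),
    fp = sum(pred == "target" & truth == "background"),
    tn = sum(pred == "background" & truth == "background"),
    fn = sum(pred == "background" & truth == "target"))
  expect_lt(abs(kappaStatistic(counts)), 0.1)
})

test_that("predicted maps recount correctly and respect nodata", {
  w <- miniWorld(sep = 4)
  ds <- assemblePixelDataset(w$cube, w$design,
                             c(sprintf("T%02d", 1:3), sprintf("B%02d", 1:5)))
  model <- trainRF(ds, seed = 3)
  cube <- w$cube
  cube@nodataMask[1:2, 1] <- TRUE
  cube@data[1:2, 1, ] <- NA_real_
  map <- predictMap(model, cube)
  expect_true(all(is.na(labelRaster(map)[1:2, 1])))
  p <- probRaster(map)
  expect_true(all(p[!is.na(p)] >= 0 & p[!is.na(p)] <= 1))
  lab <- labelRaster(map)
  expect_equal(mapAreaPercent(map),
               100 * mean(lab[!is.na(lab)] == 1L))
  # band-count mismatch
  bad <- cubeFromMatrix(matrix(rnorm(100 * 3), ncol = 3), 10, 10)
  expect_error(predictMap(model, bad), "expects")
})
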