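test_that("Kappa matches hand-evaluated cases", {
  expect_equal(kappaStatistic(confusionCounts(50, 0, 50, 0)), 1.0)
  # p_o = 0.7, p_e = 0.5 -> kappa 0.4
  expect_equal(kappaStatistic(confusionCounts(tp = 40, fp = 20, tn = 30,
                                              fn = 10)), 0.4)
  # counts proportional to independent marginals -> 0
  expect_equal(kappaStatistic(confusionCounts(tp = 12, fp = 28, tn = 42,
                                              fn = 18)), 0, tolerance = 1e-12)
  expect_error(kappaStatistic(confusionCounts(0, 0, 0, 0)), "empty")
})

test_that("F1 matches hand-evaluated cases", {
  expect_equal(f1Score(confusionCounts(10, 0, 5, 0)), 1.0)
  expect_equal(f1Score(confusionCounts(0, 7, 5, 0)), 0.0)
  expect_equal(f1Score(confusionCounts(tp = 40, fp = 20, tn = 0, fn = 10)),
               80 / 110)
  expect_error(f1Score(confusionCounts(0, 0, 9, 0)), "undefined")
})

test_that("kappa and F1 agree with exhaustive enumeration on toy maps", {
  set.seed(61)
  for (rep in 1:5) {
    truth <- sample(c("target", "background"), 100, replace = TRUE)
    pred <- sample(c(1L, 0L), 100, replace = TRUE)
    counts <- confusionCounts(
      tp = sum(pred == 1L & truth == "target"),
      fp = sum(pred == 1L & truth == "background"),
      tn = sum(pred == 0L & truth == "background"),
      fn = sum(pred == 0L & truth == "target"))
    # independent oracle: direct formulas on the 2x2 table
    n <- 100
    po <- (counts@tp + counts@tn) / n
    pe <- ((counts@tp + counts@fn) * (counts@tp + counts@fp) +
           (counts@fp + counts@tn) * (counts@fn + counts@tn)) / n^2
    expect_equal(kappaStatistic(counts), (po - pe) / (1 - pe))
    prec <- counts@tp / (counts@tp + counts@fp)
    rec <- counts@tp / (counts@tp + counts@fn)
    expect_equal(f1Score(counts), 2 * prec * rec / (prec + rec),
                 tolerance = 1e-12)
  }
})

# one tiny world shared by the stratum/zonal tests
toyMapWorld <- function() {
  labels <- matrix(0L, 10, 10)
  labels[2:5, 2:5] <- 1L
  labels[8, 8] <- 1L
  map <- new("ClassifiedMap", labels = labels,
             prob = (labels == 1L) * 1.0, gsd = 1, threshold = 0.5)
  ids <- c("T1", "T2", "T3", "B1")
  pixels <- list(
    T1 = cbind(row = 2:4, col = rep(2L, 3)),      # fully inside predicted
    T2 = cbind(row = c(5L, 6L), col = c(5L, 6L)), # half predicted
    T3 = cbind(row = 9:10, col = rep(1L, 2)),     # none predicted
    B1 = cbind(row = c(8L, 8L, 9L), col = c(8L, 9L, 9L)) # one FP of three
  )
  meta <- data.frame(
    id = ids, klass = c("target", "target", "target", "background"),
    coverPct = c(90L, 60L, 30L, 0L),
    stratum = c("80-100", "50-70", "20-40", "none"),
    role = "unassigned", centerRow = 1, centerCol = 1,
    centerX = 0, centerY = 0, stringsAsFactors = FALSE)
  design <- new("SampleDesign", meta = meta, pixels = pixels, radius = 2,
                seed = 1L)
  list(map = map, design = design,
       validation = list(target = c("T1", "T2", "T3"), background = "B1"))
}

test_that("stratum TP fractions equal a brute-force pixel recount", {
  w <- toyMapWorld()
  st <- stratumTPFraction(w$map, w$design, w$validation)
  expect_equal(unname(st$stratumTPPct["80-100"]), 100)
  expect_equal(unname(st$stratumTPPct["50-70"]), 50)
  expect_equal(unname(st$stratumTPPct["20-40"]), 0)
  expect_equal(st$backgroundFPPct, 100 / 3)
  # all-target and all-background maps
  allT <- w$map; allT@labels[] <- 1L
  stT <- stratumTPFraction(allT, w$design, w$validation)
  expect_true(all(stT$stratumTPPct == 100))
  expect_equal(stT$backgroundFPPct, 100)
  allB <- w$map; allB@labels[] <- 0L
  stB <- stratumTPFraction(allB, w$design, w$validation)
  expect_true(all(stB$stratumTPPct == 0))
  expect_equal(stB$backgroundFPPct, 0)
  # an empty stratum is reported missing, not zero
  v2 <- list(target = c("T1", "T2"), background = "B1")
  st2 <- stratumTPFraction(w$map, w$design, v2)
  expect_true(is.na(st2$stratumTPPct["20-40"]))
})

test_that("map area percentage is a simple recount", {
  labels <- matrix(c(1L, 0L), 10, 10)
  map <- new("ClassifiedMap", labels = labels, prob = labels * 1.0,
             gsd = 1, threshold = 0.5)
  expect_equal(mapAreaPercent(map), 50)
  map@labels[] <- 1L
  expect_equal(mapAreaPercent(map), 100)
  map@labels[] <- NA_integer_
  expect_error(mapAreaPercent(map), "no valid")
})

test_that("zonal confusion matches exhaustive enumeration", {
  set.seed(62)
  for (rep in 1:5) {
    labels <- matrix(sample(c(0L, 1L), 100, replace = TRUE), 10, 10)
    cover <- matrix(0, 10, 10)
    cover[3:4, 3:4] <- 1  # 4-pixel patch
    sc <- sceneFromCover(cover)
    patches <- extractTruthPatches(sc, minAreaM2 = 4)
    map <- new("ClassifiedMap", labels = labels, prob = labels * 1.0,
               gsd = 1, threshold = 0.5)
    control <- c(2L, 9L, 2L, 9L)
    got <- zonalConfusion(map, patches, control)
    inside <- matrix(FALSE, 10, 10)
    for (p in patches) inside[p$pixels] <- TRUE
    want <- enumerateZonal(labels, inside, control)
    expect_equal(got@tpArea, want$tp)
    expect_equal(got@fpArea, want$fp)
    expect_equal(got@tnArea, want$tn)
    expect_equal(got@fnArea, want$fn)
    # partition invariants hold exactly
    expect_equal(got@tpArea + got@fnArea, got@controlSpeciesArea)
    expect_equal(got@fpArea + got@tnArea, got@controlBackgroundArea)
  }
})

test_that("perfect and empty maps give degenerate zonal corners", {
  cover <- matrix(0, 10, 10)
  cover[2:5, 2:5] <- 1
  sc <- sceneFromCover(cover)
  patches <- extractTruthPatches(sc)
  inside <- cover >= 0.2
  perfect <- new("ClassifiedMap", labels = matrix(as.integer(inside), 10, 10),
                 prob = inside * 1.0, gsd = 1, threshold = 0.5)
  control <- c(1L, 10L, 1L, 10L)
  zp <- zonalConfusion(perfect, patches, control)
  expect_equal(zp@fpArea, 0)
  expect_equal(zp@fnArea, 0)
  empty <- perfect; empty@labels[] <- 0L; empty@prob[] <- 0
  ze <- zonalConfusion(empty, patches, control)
  expect_equal(ze@tpArea, 0)
  expect_equal(ze@fpArea, 0)
  expect_equal(ze@fnArea, ze@controlSpeciesArea)
  expect_error(zonalConfusion(perfect, patches, c(5L, 4L, 1L, 10L)),
               "zero extent")
  expect_error(zonalConfusion(perfect, patches, c(1L, 11L, 1L, 10L)),
               "beyond")
})

test_that("percentage conventions normalize FP by the species area", {
  areas <- new("ConfusionAreas", controlSpeciesArea = 200,
               controlBackgroundArea = 800, tpArea = 150, fpArea = 90,
               tnArea = 710, fnArea = 50)
  pct <- confusionPercentages(areas)
  expect_equal(pct@tpPct, 75)
  expect_equal(pct@fpPct, 45)   # 90 / 200, not 90 / 800
  expect_equal(pct@fnPct, 25)
  expect_equal(pct@tnPct, 89)   # 710 / 800 = 88.75, half-up
  expect_equal(pct@tpPct + pct@fnPct, 100)
  one <- confusionPercentages(areas, digits = 1)
  expect_equal(one@tnPct, 88.8)
  # degenerate full-TP case
  full <- new("ConfusionAreas", controlSpeciesArea = 100,
              controlBackgroundArea = 100, tpArea = 100, fpArea = 0,
              tnArea = 100, fnArea = 0)
  fp <- confusionPercentages(full)
  expect_equal(c(fp@tpPct, fp@fpPct), c(100, 0))
  bad <- new("ConfusionAreas", controlSpeciesArea = 0,
             controlBackgroundArea = 1, tpArea = 0, fpArea = 0,
             tnArea = 1, fnArea = 0)
  expect_error(confusionPercentages(bad), "positive")
})

test_that("half-up rounding is used for reported percentages", {
  expect_equal(coverwise:::roundHalfUp(0.5), 1)
  expect_equal(coverwise:::roundHalfUp(1.5), 2)
  expect_equal(coverwise:::roundHalfUp(2.45, 1), 2.5)
  expect_equal(coverwise:::roundHalfUp(-0.4), 0)
})

mkReport <- function(name, kappa, f1, strata, bgfp, tpPct, fpPct) {
  ca <- new("ConfusionAreas", controlSpeciesArea = 100,
            controlBackgroundArea = 100, tpArea = tpPct, fpArea = fpPct,
            tnArea = 100 - fpPct, fnArea = 100 - tpPct,
            tpPct = tpPct, fpPct = fpPct, tnPct = 100 - fpPct,
            fnPct = 100 - tpPct)
  new("EvaluationReport", scenario = name, kappa = kappa, f1 = f1,
      stratumTPPct = stats::setNames(strata, c("20-40", "50-70", "80-100")),
      backgroundFPPct = bgfp, mapAreaPct = 5, confusionAreas = ca)
}

test_that("a dominant scenario wins unanimously", {
  reports <- list(
    mkReport("A", 0.9, 0.9, c(80, 90, 95), 1, 90, 5),
    mkReport("B", 0.5, 0.6, c(40, 50, 60), 10, 60, 20),
    mkReport("C", 0.4, 0.5, c(30, 40, 50), 20, 50, 30)
  )
  sel <- selectBestScenario(reports)
  expect_equal(unname(sel$winners), rep("A", 3))
  expect_equal(sel$overall, "A")
  expect_error(selectBestScenario(reports[1]), "at least two")
})

test_that("field-map compatibility breaks ties on lower FP", {
  reports <- list(
    mkReport("X", 0.7, 0.7, c(60, 70, 80), 5, 60, 29),
    mkReport("Y", 0.6, 0.6, c(50, 60, 70), 6, 60, 28)
  )
  sel <- selectBestScenario(reports)
  expect_equal(unname(sel$winners[["c"]]), "Y")
})

test_that("majority vote follows the published winner patterns", {
  wp <- publishedWinnerPatterns()
  for (i in seq_len(nrow(wp))) {
    got <- majorityWinner(c(a = wp$accuracy_winner[i],
                            b = wp$pixels_winner[i],
                            c = wp$field_winner[i]))
    expect_equal(got, wp$chosen[i])
  }
  # all-distinct case: the end-user criterion decides
  expect_equal(majorityWinner(c(a = "P", b = "Q", c = "R")), "R")
})
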