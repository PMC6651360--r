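#' Construct a pixel-count confusion matrix
#'
#' @param tp,fp,tn,fn Nonnegative pixel counts.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))
}

#' Cohen's Kappa from a confusion matrix
#'
#' \eqn{(p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = (tp + tn)/n} and chance agreement \eqn{p_e} from the
#' products of the row and column marginals. Returns 0 when
#' \eqn{p_e = 1}.
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Value in \code{[-1, 1]}.
#' @export
kappaStatistic <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  n <- counts@tp + counts@fp + counts@tn + counts@fn
  if (n == 0) stop("empty confusion matrix")
  po <- (counts@tp + counts@tn) / n
  actPos <- counts@tp + counts@fn
  actNeg <- counts@fp + counts@tn
  prdPos <- counts@tp + counts@fp
  prdNeg <- counts@fn + counts@tn
  pe <- (actPos * prdPos + actNeg * prdNeg) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' F1 score for the target class
#'
#' \eqn{2 tp / (2 tp + fp + fn)}.
#'
#' @param counts A \linkS4class{ConfusionCounts}.
#' @return Value in \code{[0, 1]}.
#' @export
f1Score <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  denom <- 2 * counts@tp + counts@fp + counts@fn
  if (denom == 0) stop("F1 undefined: tp, fp and fn are all zero")
  2 * counts@tp / denom
}

#' Confusion counts of a map over validation polygons
#'
#' Compares the map label at every member pixel of the given polygons
#' with the polygon class. Pixels with NA labels are excluded.
#'
#' @param map A \linkS4class{ClassifiedMap}.
#' @param design A \linkS4class{SampleDesign}.
#' @param ids Polygon ids forming the validation set.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
validationCounts <- function(map, design, ids) {
  m <- polygonMeta(design)
  rows <- nrow(map@labels)
  tp <- fp <- tn <- fn <- 0
  for (id in ids) {
    px <- design@pixels[[id]]
    lab <- map@labels[rcToIndex(px, rows)]
    lab <- lab[!is.na(lab)]
    if (m$klass[match(id, m$id)] == "target") {
      tp <- tp + sum(lab == 1L)
      fn <- fn + sum(lab == 0L)
    } else {
      fp <- fp + sum(lab == 1L)
      tn <- tn + sum(lab == 0L)
    }
  }
  confusionCounts(tp, fp, tn, fn)
}

#' Correct-pixel fractions per validation cover stratum
#'
#' For each cover stratum, the percentage of pixels in that stratum's
#' validation target polygons that the map labels target; plus the
#' percentage of all background-validation pixels labelled target (the
#' false-positive line). A stratum with no validation pixels is reported
#' as NA (missing, not zero).
#'
#' @param map A \linkS4class{ClassifiedMap}.
#' @param design A \linkS4class{SampleDesign}.
#' @param validation List with id vectors \code{target} and
#'   \code{background}.
#' @return List with \code{stratumTPPct} (named numeric over the three
#'   strata) and \code{backgroundFPPct}.
#' @export
stratumTPFraction <- function(map, design, validation) {
  m <- polygonMeta(design)
  rows <- nrow(map@labels)
  labsOf <- function(ids) {
    if (!length(ids)) return(integer(0))
    lab <- unlist(lapply(ids, function(id) {
      map@labels[rcToIndex(design@pixels[[id]], rows)]
    }), use.names = FALSE)
    lab[!is.na(lab)]
  }
  stratumTPPct <- vapply(strataLevels, function(s) {
    ids <- validation$target[m$stratum[match(validation$target, m$id)] == s]
    lab <- labsOf(ids)
    if (!length(lab)) NA_real_ else 100 * mean(lab == 1L)
  }, numeric(1))
  bgLab <- labsOf(validation$background)
  list(stratumTPPct = stratumTPPct,
       backgroundFPPct = if (!length(bgLab)) NA_real_ else 100 * mean(bgLab == 1L))
}

#' Percentage of the mapped area occupied by the target species
#'
#' @param map A \linkS4class{ClassifiedMap}.
#' @return 100 x (target pixels) / (valid pixels).
#' @export
mapAreaPercent <- function(map) {
  valid <- !is.na(map@labels)
  if (!any(valid)) stop("map has no valid pixels")
  100 * mean(map@labels[valid] == 1L)
}

#' Centred square control area
#'
#' @param dims Raster dimensions \code{c(rows, cols)}.
#' @param sideM Side length in metres.
#' @param gsd Ground sample distance in metres.
#' @return Integer vector \code{c(rowMin, rowMax, colMin, colMax)}.
#' @export
controlAreaSquare <- function(dims, sideM, gsd = 1) {
  side <- round(sideM / gsd)
  if (side < 1 || side > min(dims))
    stop("control area does not fit in the raster")
  r0 <- (dims[1] - side) %/% 2 + 1L
  c0 <- (dims[2] - side) %/% 2 + 1L
  c(rowMin = r0, rowMax = r0 + side - 1L,
    colMin = c0, colMax = c0 + side - 1L)
}

#' Zonal confusion of a map against field-mapped truth patches
#'
#' Restricts to pixels whose centres lie inside the control area;
#' "inside" means membership in any truth patch. TP/FP/TN/FN areas are
#' pixel counts times gsd^2; the control species area is the patch area
#' inside the control square, the control background area the remainder.
#' Pixels with NA map labels are excluded from all groups.
#'
#' @param map A \linkS4class{ClassifiedMap}.
#' @param patches Truth patches from \code{\link{extractTruthPatches}}.
#' @param controlArea Integer vector \code{c(rowMin, rowMax, colMin,
#'   colMax)}; see \code{\link{controlAreaSquare}}.
#' @return A \linkS4class{ConfusionAreas} (percentage slots unfilled).
#' @export
zonalConfusion <- function(map, patches, controlArea) {
  stopifnot(is(map, "ClassifiedMap"))
  ca <- as.integer(controlArea)
  if (ca[2] < ca[1] || ca[4] < ca[3]) stop("control area has zero extent")
  d <- dim(map@labels)
  if (ca[1] < 1 || ca[2] > d[1] || ca[3] < 1 || ca[4] > d[2])
    stop("control area extends beyond the raster")
  inControl <- matrix(FALSE, d[1], d[2])
  inControl[ca[1]:ca[2], ca[3]:ca[4]] <- TRUE
  inPatch <- matrix(FALSE, d[1], d[2])
  for (p in patches) inPatch[p$pixels] <- TRUE
  use <- inControl & !is.na(map@labels)
  pred <- map@labels == 1L
  a <- map@gsd^2
  tp <- sum(use & inPatch & pred, na.rm = TRUE)
  fn <- sum(use & inPatch & !pred, na.rm = TRUE)
  fp <- sum(use & !inPatch & pred, na.rm = TRUE)
  tn <- sum(use & !inPatch & !pred, na.rm = TRUE)
  new("ConfusionAreas",
      controlSpeciesArea = (tp + fn) * a,
      controlBackgroundArea = (fp + tn) * a,
      tpArea = tp * a, fpArea = fp * a, tnArea = tn * a, fnArea = fn * a)
}

#' Fill the percentage columns of a zonal confusion
#'
#' Uses the field-mapping normalization convention: TP, FP and FN are
#' expressed as percentages of the control species area (the area of
#' field-mapped patches inside the control square), while TN is a
#' percentage of the control background area. Note that FP is normalized
#' by the species area, not the background area -- overestimation is
#' reported relative to how much of the species is actually there, so FP
#' percentages above 100 are possible for heavily overestimated maps.
#' Rounding is half-up; \code{digits = 1} gives the one-decimal variant
#' used in running-text figures.
#'
#' @param areas A \linkS4class{ConfusionAreas}.
#' @param digits Decimal places (0 for table-style integers, 1 for
#'   text-style).
#' @return The \linkS4class{ConfusionAreas} with percentage slots filled.
#' @export
confusionPercentages <- function(areas, digits = 0) {
  stopifnot(is(areas, "ConfusionAreas"))
  if (areas@controlSpeciesArea <= 0)
    stop("control species area must be positive")
  if (areas@controlBackgroundArea <= 0)
    stop("control background area must be positive")
  sp <- areas@controlSpeciesArea
  bg <- areas@controlBackgroundArea
  areas@tpPct <- roundHalfUp(100 * areas@tpArea / sp, digits)
  areas@fpPct <- roundHalfUp(100 * areas@fpArea / sp, digits)
  areas@fnPct <- roundHalfUp(100 * areas@fnArea / sp, digits)
  areas@tnPct <- roundHalfUp(100 * areas@tnArea / bg, digits)
  areas
}

#' Assemble the full evaluation report for one scenario
#'
#' @param scenario Scenario name.
#' @param map A \linkS4class{ClassifiedMap}.
#' @param design A \linkS4class{SampleDesign}.
#' @param validation List with \code{target} and \code{background} ids.
#' @param patches Truth patches.
#' @param controlArea Control-area bounds.
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateScenario <- function(scenario, map, design, validation, patches,
                             controlArea) {
  counts <- validationCounts(map, design,
                             c(validation$target, validation$background))
  st <- stratumTPFraction(map, design, validation)
  areas <- confusionPercentages(zonalConfusion(map, patches, controlArea))
  new("EvaluationReport",
      scenario = scenario,
      kappa = kappaStatistic(counts),
      f1 = f1Score(counts),
      stratumTPPct = st$stratumTPPct,
      backgroundFPPct = st$backgroundFPPct,
      mapAreaPct = mapAreaPercent(map),
      confusionAreas = areas)
}

#' Pick per-criterion winners and the overall best scenario
#'
#' Three per-criterion winners: (a) highest mean of Kappa and F1; (b)
#' highest mean per-stratum true-positive percentage penalized by the
#' background false-positive percentage (score = mean stratum TP -
#' background FP); (c) field-map compatibility: highest zonal TP
#' percentage, lower FP percentage breaking ties. The overall winner is
#' the majority vote of the three; when all three disagree, criterion
#' (c) -- the end-user criterion -- decides.
#'
#' @param reports List of \linkS4class{EvaluationReport} objects (at
#'   least two).
#' @return List with \code{winners} (named character vector a, b, c) and
#'   \code{overall}.
#' @export
selectBestScenario <- function(reports) {
  if (length(reports) < 2L) stop("need at least two reports")
  nm <- unname(vapply(reports, function(r) r@scenario, character(1)))
  accScore <- vapply(reports, function(r) (r@kappa + r@f1) / 2, numeric(1))
  pixScore <- vapply(reports, function(r) {
    mean(r@stratumTPPct, na.rm = TRUE) - r@backgroundFPPct
  }, numeric(1))
  tp <- vapply(reports, function(r) r@confusionAreas@tpPct, numeric(1))
  fp <- vapply(reports, function(r) r@confusionAreas@fpPct, numeric(1))
  a <- nm[which.max(accScore)]
  b <- nm[which.max(pixScore)]
  cIdx <- order(-tp, fp)[1]
  c_ <- nm[cIdx]
  winners <- c(a = a, b = b, c = c_)
  list(winners = winners, overall = majorityWinner(winners))
}

#' Majority vote over the three per-criterion winners
#'
#' @param winners Named character vector with entries a, b, c (accuracy
#'   measures, correct-pixel analysis, field-map compatibility).
#' @return The scenario named by at least two criteria, or the field-map
#'   compatibility winner when all three disagree.
#' @export
majorityWinner <- function(winners) {
  tab <- table(winners)
  if (max(tab) >= 2) names(tab)[which.max(tab)] else unname(winners[["c"]])
}
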