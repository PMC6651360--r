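#' Rasterize a circular plot under the pixel-centre-in rule
#'
#' Returns the pixels whose centres lie within Euclidean distance
#' \code{radius} of the circle centre. On a 1 m grid with the centre on a
#' pixel centre, a 2 m radius yields 13 pixels (field-campaign bookkeeping
#' nominally counts about 15 per plot).
#'
#' @param center Map coordinates \code{c(x, y)} of the circle centre.
#' @param radius Radius in metres.
#' @param geotransform Length-6 geotransform of the raster.
#' @param dims Raster dimensions \code{c(rows, cols)}.
#' @return Integer matrix with columns row, col; zero rows (with a
#'   warning) when the circle lies entirely outside the raster.
#' @export
rasterizeCircle <- function(center, radius, geotransform, dims) {
  if (radius <= 0) stop("radius must be positive")
  px <- abs(geotransform[2])
  py <- abs(geotransform[6])
  rc <- mapToRowCol(center[1], center[2], geotransform)
  rowRange <- floor(rc[1] - radius / py - 1):ceiling(rc[1] + radius / py + 1)
  colRange <- floor(rc[2] - radius / px - 1):ceiling(rc[2] + radius / px + 1)
  rowRange <- rowRange[rowRange >= 1 & rowRange <= dims[1]]
  colRange <- colRange[colRange >= 1 & colRange <= dims[2]]
  if (!length(rowRange) || !length(colRange)) {
    warning("circle lies entirely outside the raster")
    return(cbind(row = integer(0), col = integer(0)))
  }
  grid <- expand.grid(row = rowRange, col = colRange)
  xy <- pixelCenterXY(grid$row, grid$col, geotransform)
  keep <- (xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2 <= radius^2
  if (!any(keep)) {
    warning("circle contains no pixel centre inside the raster")
    return(cbind(row = integer(0), col = integer(0)))
  }
  as.matrix(grid[keep, c("row", "col"), drop = FALSE])
}

#' Annotate a polygon with its decile cover percentage
#'
#' Mean target cover over the member pixels, times 100, rounded half-up
#' to the nearest multiple of 10. Field cover estimates are recorded on a
#' 10\% grid; the three strata (20-40, 50-70, 80-100\%) are exhaustive
#' over that grid for covers of at least 20\%.
#'
#' @param pixels Integer matrix of member pixels (columns row, col).
#' @param scene A \linkS4class{CoverScene}.
#' @return Integer cover percentage on the decile grid.
#' @export
annotateCover <- function(pixels, scene) {
  if (!nrow(pixels)) stop("polygon has no member pixels")
  idx <- rcToIndex(pixels, nrow(scene@cover))
  decileCoverPct(mean(scene@cover[idx]))
}

# Disk offsets (in pixels) under the pixel-centre-in rule for a circle
# centred on a pixel centre.
diskOffsets <- function(radius, gsd) {
  k <- floor(radius / gsd)
  og <- expand.grid(dr = -k:k, dc = -k:k)
  og[og$dr^2 + og$dc^2 <= (radius / gsd)^2, , drop = FALSE]
}

# Mean of `field` over the disk around each pixel; NA where the disk
# leaves the raster.
diskMean <- function(field, offsets) {
  rows <- nrow(field)
  cols <- ncol(field)
  acc <- matrix(0, rows, cols)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]
    dc <- offsets$dc[i]
    shifted <- matrix(NA_real_, rows, cols)
    rSrc <- max(1, 1 + dr):min(rows, rows + dr)
    cSrc <- max(1, 1 + dc):min(cols, cols + dc)
    shifted[rSrc - dr, cSrc - dc] <- field[rSrc, cSrc]
    acc <- acc + shifted
  }
  acc / nrow(offsets)
}

#' Place and annotate reference polygons on a simulated scene
#'
#' Seeded rejection sampling over pixel-centre candidate locations.
#' Target polygons are drawn so that their annotated cover percentage
#' falls in the requested stratum (counts per stratum given by
#' \code{strataCounts}); background polygons are drawn where every member
#' pixel has exactly zero target cover. Centres respect a minimum
#' spacing (default 10 m), which also guarantees pairwise pixel
#' disjointness for the default 2 m radius.
#'
#' @param scene A \linkS4class{CoverScene}.
#' @param nTarget Number of target polygons (default 110).
#' @param strataCounts Per-stratum target counts for 20-40, 50-70 and
#'   80-100\% (default 30, 30, 50).
#' @param nBackground Number of background polygons (default 200).
#' @param seed Integer seed.
#' @param radius Plot radius in metres (default 2).
#' @param minSpacing Minimum centre spacing in metres (default 10).
#' @return A \linkS4class{SampleDesign}.
#' @export
placeReferencePolygons <- function(scene, nTarget = 110L,
                                   strataCounts = c(30L, 30L, 50L),
                                   nBackground = 200L, seed = 1L,
                                   radius = 2, minSpacing = 10) {
  stopifnot(is(scene, "CoverScene"))
  if (length(strataCounts) != 3L || sum(strataCounts) != nTarget)
    stop("strataCounts must have length 3 and sum to nTarget")
  rows <- nrow(scene@cover)
  cols <- ncol(scene@cover)
  gt <- defaultGeotransform(rows, scene@gsd)
  off <- diskOffsets(radius, scene@gsd)
  k <- max(abs(c(off$dr, off$dc)))

  meanCover <- diskMean(scene@cover, off)
  anyCover <- diskMean((scene@cover > 0) * 1, off)
  inBounds <- matrix(FALSE, rows, cols)
  if (rows > 2 * k && cols > 2 * k)
    inBounds[(k + 1):(rows - k), (k + 1):(cols - k)] <- TRUE
  covPct <- matrix(NA_integer_, rows, cols)
  okc <- inBounds & !is.na(meanCover)
  covPct[okc] <- decileCoverPct(meanCover[okc])

  set.seed(as.integer(seed))
  accX <- numeric(0)
  accY <- numeric(0)
  minSp2 <- minSpacing^2
  takeCandidates <- function(candIdx, nWanted, what) {
    chosen <- integer(0)
    for (ci in candIdx[sample.int(length(candIdx))]) {
      if (length(chosen) == nWanted) break
      r <- ((ci - 1L) %% rows) + 1L
      co <- ((ci - 1L) %/% rows) + 1L
      xy <- pixelCenterXY(r, co, gt)
      if (length(accX) &&
          min((accX - xy[1])^2 + (accY - xy[2])^2) < minSp2) next
      accX <<- c(accX, xy[1])
      accY <<- c(accY, xy[2])
      chosen <- c(chosen, ci)
    }
    if (length(chosen) < nWanted)
      stop("could not place ", nWanted, " ", what, " polygons (placed ",
           length(chosen), "); scene too small or cover too sparse")
    chosen
  }

  # rarest stratum first: 80-100, then 50-70, 20-40, then background
  order_ <- c("80-100", "50-70", "20-40")
  counts <- stats::setNames(strataCounts, strataLevels)[order_]
  targetIdx <- integer(0)
  for (s in order_) {
    cand <- which(okc & stratumOf(covPct) == s)
    targetIdx <- c(targetIdx, takeCandidates(cand, counts[[s]],
                                             paste0("stratum ", s, " target")))
  }
  bgCand <- which(inBounds & !is.na(anyCover) & anyCover == 0)
  bgIdx <- takeCandidates(bgCand, nBackground, "background")

  buildMeta <- function(idx, klass, prefix) {
    r <- ((idx - 1L) %% rows) + 1L
    co <- ((idx - 1L) %/% rows) + 1L
    xy <- pixelCenterXY(r, co, gt)
    ids <- sprintf("%s%03d", prefix, seq_along(idx))
    px <- lapply(seq_along(idx), function(i) {
      cbind(row = r[i] + off$dr, col = co[i] + off$dc)
    })
    names(px) <- ids
    cp <- if (klass == "target")
      vapply(px, annotateCover, integer(1), scene = scene)
    else rep(0L, length(idx))
    list(meta = data.frame(
      id = ids, klass = klass, coverPct = cp,
      stratum = if (klass == "target") stratumOf(cp) else "none",
      role = "unassigned",
      centerRow = r, centerCol = co,
      centerX = xy[, 1], centerY = xy[, 2],
      stringsAsFactors = FALSE
    ), pixels = px)
  }
  tg <- buildMeta(targetIdx, "target", "T")
  bg <- buildMeta(bgIdx, "background", "B")
  new("SampleDesign",
      meta = rbind(tg$meta, bg$meta),
      pixels = c(tg$pixels, bg$pixels),
      radius = radius, seed = as.integer(seed))
}

#' Random polygon-level 50/50 split (Stage 0)
#'
#' Splits the full design into training and validation halves at the
#' polygon level (all pixels of a polygon share its role), without cover
#' stratification: 55 target + 100 background polygons per side under the
#' default design.
#'
#' @param design A \linkS4class{SampleDesign}.
#' @param seed Integer seed.
#' @return List with character-id vectors \code{train} and
#'   \code{validation}.
#' @export
splitStage0 <- function(design, seed = 1L) {
  m <- polygonMeta(design)
  set.seed(as.integer(seed))
  pick <- function(ids) sample(ids, length(ids) %/% 2L)
  tTrain <- pick(m$id[m$klass == "target"])
  bTrain <- pick(m$id[m$klass == "background"])
  train <- c(tTrain, bTrain)
  list(train = train, validation = setdiff(m$id, train))
}

#' Build the fixed validation set for Stages 1 and 2
#'
#' Selects 10 target polygons from each of the three cover strata plus
#' 100 background polygons, spread by greedy farthest-point selection on
#' the polygon centres. The set is fixed once per experiment and reused
#' unchanged across all Stage 1/2 scenarios.
#'
#' @param design A \linkS4class{SampleDesign}.
#' @param seed Integer seed (chooses the greedy starting polygon).
#' @param nPerStratum Target polygons per stratum (default 10).
#' @param nBackground Background polygons (default 100).
#' @return List with id vectors \code{target} and \code{background}.
#' @export
buildFixedValidation <- function(design, seed = 1L, nPerStratum = 10L,
                                 nBackground = 100L) {
  m <- polygonMeta(design)
  set.seed(as.integer(seed))
  farthest <- function(ids, n) {
    if (length(ids) < n)
      stop("insufficient polygons: need ", n, ", have ", length(ids))
    x <- m$centerX[match(ids, m$id)]
    y <- m$centerY[match(ids, m$id)]
    chosen <- sample.int(length(ids), 1L)
    dmin <- (x - x[chosen])^2 + (y - y[chosen])^2
    while (length(chosen) < n) {
      nxt <- which.max(dmin)
      chosen <- c(chosen, nxt)
      dmin <- pmin(dmin, (x - x[nxt])^2 + (y - y[nxt])^2)
    }
    ids[chosen]
  }
  target <- unlist(lapply(strataLevels, function(s) {
    farthest(m$id[m$klass == "target" & m$stratum == s], nPerStratum)
  }), use.names = FALSE)
  background <- farthest(m$id[m$klass == "background"], nBackground)
  list(target = target, background = background)
}
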