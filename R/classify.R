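#' Assert that training and validation polygons are disjoint
#'
#' Polygon-level leakage guard: every pixel of a polygon is used for
#' training or for validation, never both.
#'
#' @param trainIds,validationIds Character vectors of polygon ids.
#' @return Invisibly TRUE; errors on overlap.
#' @export
assertNoLeakage <- function(trainIds, validationIds) {
  shared <- intersect(trainIds, validationIds)
  if (length(shared))
    stop("polygons assigned to both training and validation: ",
         paste(utils::head(shared, 5), collapse = ", "))
  invisible(TRUE)
}

#' Assemble a per-pixel dataset from polygons
#'
#' One feature row per member pixel of every listed polygon, labelled by
#' the polygon's class. Target polygons label all their pixels as target
#' regardless of cover: models are trained on whole polygons, which is
#' exactly what makes low-cover training polygons inject mixed spectra
#' into the target class.
#'
#' @param mnfCube A k-band \linkS4class{HyperCube} of MNF components.
#' @param design A \linkS4class{SampleDesign}.
#' @param ids Character vector of polygon ids to include.
#' @return A \linkS4class{PixelDataset}.
#' @export
assemblePixelDataset <- function(mnfCube, design, ids) {
  stopifnot(is(mnfCube, "HyperCube"), is(design, "SampleDesign"))
  m <- polygonMeta(design)
  if (!all(ids %in% m$id)) stop("unknown polygon ids")
  d <- dim(mnfCube@data)
  X <- matrix(mnfCube@data, nrow = d[1] * d[2], ncol = d[3])
  feat <- vector("list", length(ids))
  lab <- character(0)
  pid <- character(0)
  for (i in seq_along(ids)) {
    px <- design@pixels[[ids[i]]]
    if (any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2]))
      stop("polygon ", ids[i], " has pixels outside the raster")
    feat[[i]] <- X[rcToIndex(px, d[1]), , drop = FALSE]
    klass <- m$klass[match(ids[i], m$id)]
    lab <- c(lab, rep(klass, nrow(px)))
    pid <- c(pid, rep(ids[i], nrow(px)))
  }
  features <- do.call(rbind, feat)
  if (is.null(features)) features <- matrix(numeric(0), 0, d[3])
  colnames(features) <- paste0("comp_", seq_len(d[3]))
  if (nrow(features)) {
    constant <- apply(features, 2, function(v) diff(range(v)) == 0)
    if (any(constant))
      warning("constant feature columns: ",
              paste(colnames(features)[constant], collapse = ", "))
  }
  new("PixelDataset", features = features,
      labels = factor(lab, levels = c("background", "target")),
      polygonId = pid)
}

#' Train the binary Random Forest
#'
#' 100 classification trees, Gini impurity splits, square root of the
#' number of features tried at each split, bootstrap sampling; all other
#' hyperparameters at their common defaults (no tuning). Class imbalance
#' is deliberately left uncorrected.
#'
#' @param dataset A \linkS4class{PixelDataset} containing both classes.
#' @param seed Integer seed.
#' @param ntree Number of trees (default 100).
#' @return A \code{randomForest} model.
#' @export
trainRF <- function(dataset, seed = 1L, ntree = 100L) {
  stopifnot(is(dataset, "PixelDataset"))
  if (nrow(dataset@features) == 0L) stop("empty training dataset")
  if (nlevels(droplevels(dataset@labels)) < 2L)
    stop("training data contain a single class")
  set.seed(as.integer(seed))
  randomForest::randomForest(
    x = dataset@features, y = dataset@labels,
    ntree = as.integer(ntree),
    mtry = floor(sqrt(ncol(dataset@features)))
  )
}

#' Predict a full-scene presence-absence map
#'
#' Per-pixel fraction of trees voting target, thresholded (default 0.5,
#' i.e. majority vote) into a binary map. Nodata pixels propagate as NA.
#'
#' @param model A model from \code{\link{trainRF}}.
#' @param mnfCube A \linkS4class{HyperCube} with the same number of bands
#'   as the training features.
#' @param threshold Decision threshold on the vote fraction.
#' @return A \linkS4class{ClassifiedMap}.
#' @export
predictMap <- function(model, mnfCube, threshold = 0.5) {
  stopifnot(is(mnfCube, "HyperCube"))
  nFeat <- length(model$forest$ncat)
  if (nBands(mnfCube) != nFeat)
    stop("cube has ", nBands(mnfCube), " bands but the model expects ",
         nFeat, " features")
  vp <- validPixelMatrix(mnfCube)
  colnames(vp$X) <- paste0("comp_", seq_len(ncol(vp$X)))
  prob <- rep(NA_real_, vp$dim[1] * vp$dim[2])
  if (nrow(vp$X)) {
    p <- stats::predict(model, vp$X, type = "prob")[, "target"]
    prob[vp$index] <- p
  }
  probM <- matrix(prob, vp$dim[1], vp$dim[2])
  lab <- matrix(NA_integer_, vp$dim[1], vp$dim[2])
  lab[!is.na(probM)] <- as.integer(probM[!is.na(probM)] >= threshold)
  new("ClassifiedMap", labels = lab, prob = probM, gsd = mnfCube@gsd,
      threshold = threshold)
}
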