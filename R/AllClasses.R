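#' @import methods
NULL

#' SpectralLibrary: endmember reflectance spectra
#'
#' Holds the pure spectral signatures (endmembers) used for linear mixing:
#' one target-species endmember and several background endmembers, sampled
#' on a common ascending wavelength grid.
#'
#' @slot wavelengths Numeric vector of band-centre wavelengths in nm,
#'   strictly increasing.
#' @slot spectra Matrix (endmembers x bands) of reflectance values in
#'   \code{[0, 1]}; rownames are the endmember labels.
#' @slot target Character scalar, the label of the single target-species
#'   endmember.
#' @exportClass SpectralLibrary
setClass("SpectralLibrary",
  representation(
    wavelengths = "numeric",
    spectra = "matrix",
    target = "character"
  )
)

setValidity("SpectralLibrary", function(object) {
  msg <- character()
  if (length(object@wavelengths) != ncol(object@spectra))
    msg <- c(msg, "length(wavelengths) must equal ncol(spectra)")
  if (any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(object@spectra < 0 | object@spectra > 1))
    msg <- c(msg, "reflectance values must lie in [0, 1]")
  if (is.null(rownames(object@spectra)))
    msg <- c(msg, "spectra must have rownames (endmember labels)")
  if (length(object@target) != 1L ||
      sum(rownames(object@spectra) == object@target) != 1L)
    msg <- c(msg, "exactly one endmember must be the target species")
  if (length(msg)) msg else TRUE
})

#' CoverScene: simulated ground truth of target-species cover
#'
#' The per-pixel target cover fraction, the convex background composition
#' at each pixel, and (once extracted) the field-mappable truth patches.
#' This object is the simulation ground truth against which sampling and
#' classification are assessed.
#'
#' @slot cover Numeric matrix (rows x cols), target cover fraction in
#'   \code{[0, 1]}.
#' @slot backgroundWeights Numeric array (rows x cols x n_background) of
#'   nonnegative per-pixel weights summing to 1 over the third dimension.
#' @slot gsd Ground sample distance in metres (pixel edge length).
#' @slot truthPatches List of truth patches (see
#'   \code{\link{extractTruthPatches}}); may be empty until extracted.
#' @exportClass CoverScene
setClass("CoverScene",
  representation(
    cover = "matrix",
    backgroundWeights = "array",
    gsd = "numeric",
    truthPatches = "list"
  ),
  prototype(gsd = 1, truthPatches = list())
)

setValidity("CoverScene", function(object) {
  msg <- character()
  if (any(object@cover < 0 | object@cover > 1))
    msg <- c(msg, "cover must lie in [0, 1]")
  d <- dim(object@backgroundWeights)
  if (length(d) != 3L || d[1] != nrow(object@cover) || d[2] != ncol(object@cover))
    msg <- c(msg, "backgroundWeights must be rows x cols x n_background")
  else {
    w <- object@backgroundWeights
    if (any(w < -1e-9))
      msg <- c(msg, "background weights must be nonnegative")
    s <- apply(w, c(1, 2), sum)
    if (max(abs(s - 1)) > 1e-6)
      msg <- c(msg, "background weights must sum to 1 per pixel")
  }
  if (length(object@gsd) != 1L || object@gsd <= 0)
    msg <- c(msg, "gsd must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' HyperCube: multiband reflectance raster
#'
#' Carrier for raw, smoothed and MNF-transformed imagery. Data are stored
#' rows x cols x bands; the geotransform maps (row, col) to map
#' coordinates GDAL-style.
#'
#' @slot data Numeric array (rows x cols x bands).
#' @slot wavelengths Numeric vector, one entry per band (nm for
#'   reflectance cubes, component index for transformed cubes).
#' @slot gsd Ground sample distance in metres.
#' @slot geotransform Numeric vector of length 6,
#'   \code{c(x0, dx, 0, y0, 0, dy)} with \code{dy < 0} (north-up).
#' @slot nodataMask Logical matrix (rows x cols); TRUE marks invalid
#'   pixels.
#' @exportClass HyperCube
setClass("HyperCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    gsd = "numeric",
    geotransform = "numeric",
    nodataMask = "matrix"
  )
)

setValidity("HyperCube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a rows x cols x bands array")
  else {
    if (length(object@wavelengths) != d[3])
      msg <- c(msg, "length(wavelengths) must equal the number of bands")
    if (!identical(dim(object@nodataMask), d[1:2]))
      msg <- c(msg, "nodataMask must match the spatial dimensions")
    valid <- !object@nodataMask
    if (any(valid) && !all(is.finite(object@data[rep(valid, d[3])])))
      msg <- c(msg, "values outside the nodata mask must be finite")
  }
  if (length(object@geotransform) != 6L)
    msg <- c(msg, "geotransform must have length 6")
  if (length(msg)) msg else TRUE
})

#' MNFResult: Minimum Noise Fraction decomposition
#'
#' @slot forwardTransform Matrix (bands x bands); column j holds the
#'   loading vector of component j. Components are computed as
#'   \code{t(x - center) \%*\% forwardTransform}.
#' @slot eigenvalues Nonincreasing generalized eigenvalues (SNR-related).
#' @slot components \linkS4class{HyperCube} of transformed bands, ordered
#'   by eigenvalue.
#' @slot noiseCov,signalCov Band x band noise and total covariance.
#' @slot center Band means used for centering.
#' @exportClass MNFResult
setClass("MNFResult",
  representation(
    forwardTransform = "matrix",
    eigenvalues = "numeric",
    components = "HyperCube",
    noiseCov = "matrix",
    signalCov = "matrix",
    center = "numeric"
  )
)

setValidity("MNFResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be nonincreasing")
  b <- length(object@eigenvalues)
  if (!identical(dim(object@forwardTransform), c(b, b)))
    msg <- c(msg, "forwardTransform must be bands x bands")
  if (length(msg)) msg else TRUE
})

#' SampleDesign: reference polygons for training and validation
#'
#' Circular reference plots (default radius 2 m) for the target species
#' and the background class, annotated with cover percentage (decile
#' grid), cover stratum and pixel membership.
#'
#' @slot meta A data.frame with one row per polygon: \code{id},
#'   \code{klass} ("target"/"background"), \code{coverPct} (0-100 on a
#'   10\% grid), \code{stratum} ("20-40", "50-70", "80-100" or "none"),
#'   \code{role}, \code{centerRow}, \code{centerCol}, \code{centerX},
#'   \code{centerY}.
#' @slot pixels Named list (by polygon id) of integer matrices with
#'   columns row, col: the member pixels under the pixel-centre-in rule.
#' @slot radius Plot radius in metres.
#' @slot seed Integer seed used for placement.
#' @exportClass SampleDesign
setClass("SampleDesign",
  representation(
    meta = "data.frame",
    pixels = "list",
    radius = "numeric",
    seed = "integer"
  )
)

setValidity("SampleDesign", function(object) {
  msg <- character()
  need <- c("id", "klass", "coverPct", "stratum", "role",
            "centerRow", "centerCol", "centerX", "centerY")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta must contain columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@meta$id))
      msg <- c(msg, "polygon ids must be unique")
    if (!all(object@meta$id %in% names(object@pixels)))
      msg <- c(msg, "every polygon needs a pixel list entry")
    tg <- object@meta$klass == "target"
    if (any(object@meta$coverPct[tg] < 20))
      msg <- c(msg, "target polygons must have coverPct >= 20")
    if (any(object@meta$coverPct %% 10 != 0))
      msg <- c(msg, "coverPct must lie on the 10% grid")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: one training-set scenario
#'
#' @slot stage Integer 0, 1 or 2.
#' @slot name Scenario name (e.g. "SC1", "SC1_40").
#' @slot coverRange Inclusive cover range (percent) allowed for target
#'   training polygons.
#' @slot nTargetTrain,nBackgroundTrain Training-set sizes (polygons).
#' @slot seed Integer seed for polygon selection.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(
    stage = "integer",
    name = "character",
    coverRange = "numeric",
    nTargetTrain = "integer",
    nBackgroundTrain = "integer",
    seed = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (!object@stage %in% 0:2) msg <- c(msg, "stage must be 0, 1 or 2")
  if (length(object@coverRange) != 2L || object@coverRange[1] > object@coverRange[2])
    msg <- c(msg, "coverRange must be an inclusive [lo, hi] pair")
  if (object@stage == 2L && !object@nTargetTrain %in% c(20L, 30L, 40L))
    msg <- c(msg, "Stage-2 target training size must be 20, 30 or 40")
  if (length(msg)) msg else TRUE
})

#' PixelDataset: per-pixel features and labels for classification
#'
#' @slot features Numeric matrix (pixels x k features).
#' @slot labels Factor with levels \code{background}, \code{target}.
#' @slot polygonId Character vector, the polygon each pixel belongs to.
#' @exportClass PixelDataset
setClass("PixelDataset",
  representation(
    features = "matrix",
    labels = "factor",
    polygonId = "character"
  )
)

setValidity("PixelDataset", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (length(object@labels) != n || length(object@polygonId) != n)
    msg <- c(msg, "labels and polygonId must match nrow(features)")
  if (!identical(levels(object@labels), c("background", "target")))
    msg <- c(msg, "labels must be a factor with levels background, target")
  if (length(msg)) msg else TRUE
})

#' ClassifiedMap: binary presence-absence map with vote fractions
#'
#' @slot labels Integer matrix (rows x cols): 1 = target, 0 = background,
#'   NA = nodata.
#' @slot prob Numeric matrix, fraction of trees voting target.
#' @slot gsd Ground sample distance in metres.
#' @slot threshold Decision threshold on the vote fraction.
#' @exportClass ClassifiedMap
setClass("ClassifiedMap",
  representation(
    labels = "matrix",
    prob = "matrix",
    gsd = "numeric",
    threshold = "numeric"
  ),
  prototype(threshold = 0.5)
)

setValidity("ClassifiedMap", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), dim(object@prob)))
    msg <- c(msg, "labels and prob must have identical dimensions")
  v <- !is.na(object@prob)
  if (any(v) && (min(object@prob[v]) < 0 || max(object@prob[v]) > 1))
    msg <- c(msg, "prob must lie in [0, 1]")
  ok <- is.na(object@labels) | object@labels %in% c(0L, 1L)
  if (!all(ok)) msg <- c(msg, "labels must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' ConfusionCounts: pixel-count confusion matrix (validation evaluation)
#'
#' @slot tp,fp,tn,fn Nonnegative pixel counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || any(v < 0) || any(!is.finite(v)))
    "tp, fp, tn, fn must be nonnegative finite scalars"
  else TRUE
})

#' ConfusionAreas: zonal confusion against field-mapped truth
#'
#' Areas (m^2) of the four zonal groups inside a control area, plus the
#' percentage columns under the field-mapping normalization convention:
#' TP, FP and FN are normalized by the control species area, TN by the
#' control background area.
#'
#' @slot controlSpeciesArea,controlBackgroundArea Control-area partition
#'   in m^2 (inside / outside field-mapped species patches).
#' @slot tpArea,fpArea,tnArea,fnArea Group areas in m^2.
#' @slot tpPct,fpPct,tnPct,fnPct Percentages (NA until
#'   \code{\link{confusionPercentages}} fills them).
#' @exportClass ConfusionAreas
setClass("ConfusionAreas",
  representation(
    controlSpeciesArea = "numeric",
    controlBackgroundArea = "numeric",
    tpArea = "numeric", fpArea = "numeric",
    tnArea = "numeric", fnArea = "numeric",
    tpPct = "numeric", fpPct = "numeric",
    tnPct = "numeric", fnPct = "numeric"
  ),
  prototype(tpPct = NA_real_, fpPct = NA_real_, tnPct = NA_real_, fnPct = NA_real_)
)

setValidity("ConfusionAreas", function(object) {
  msg <- character()
  a <- c(object@tpArea, object@fpArea, object@tnArea, object@fnArea)
  if (any(a < 0)) msg <- c(msg, "areas must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: the three assessment criteria for one scenario
#'
#' @slot scenario Scenario name.
#' @slot kappa Cohen's Kappa on validation pixels.
#' @slot f1 F1 score for the target class on validation pixels.
#' @slot stratumTPPct Named numeric ("20-40", "50-70", "80-100"):
#'   percentage of correctly classified target pixels per validation
#'   cover stratum (NA where a stratum has no validation pixels).
#' @slot backgroundFPPct Percentage of background-validation pixels
#'   labelled target.
#' @slot mapAreaPct Percentage of valid map pixels labelled target.
#' @slot confusionAreas \linkS4class{ConfusionAreas} for the control area.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(
    scenario = "character",
    kappa = "numeric",
    f1 = "numeric",
    stratumTPPct = "numeric",
    backgroundFPPct = "numeric",
    mapAreaPct = "numeric",
    confusionAreas = "ConfusionAreas"
  )
)

#' ExperimentConfig: one self-contained experiment definition
#'
#' All scene, library, sampling, MNF, classifier and scenario parameters,
#' plus the master seed from which every stage seed is derived.
#'
#' @slot rows,cols Scene size in pixels.
#' @slot bands Number of spectral bands.
#' @slot gsd Ground sample distance (m).
#' @slot prevalence Target fraction of pixels with cover >= 0.2.
#' @slot correlationLengthM Gaussian correlation length of the cover
#'   field (m).
#' @slot noiseSd Additive sensor noise SD (reflectance units).
#' @slot nBackgroundEndmembers Number of background endmembers.
#' @slot separability Spectral separability scale between target and
#'   background endmembers.
#' @slot nTarget,nBackground Reference polygon counts.
#' @slot strataCounts Target polygon counts per stratum (20-40, 50-70,
#'   80-100).
#' @slot radius Reference polygon radius (m).
#' @slot minSpacing Minimum distance between polygon centres (m).
#' @slot mnfK Number of MNF components kept.
#' @slot rfTrees Number of Random Forest trees.
#' @slot controlSideM Side length of the centred square control area (m).
#' @slot librarySeed Integer seed of the spectral library (fixed study
#'   condition).
#' @slot masterSeed Integer master seed for everything else.
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(
    rows = "integer", cols = "integer", bands = "integer",
    gsd = "numeric",
    prevalence = "numeric", correlationLengthM = "numeric",
    noiseSd = "numeric",
    nBackgroundEndmembers = "integer", separability = "numeric",
    nTarget = "integer", nBackground = "integer",
    strataCounts = "integer",
    radius = "numeric", minSpacing = "numeric",
    mnfK = "integer", rfTrees = "integer",
    controlSideM = "numeric",
    librarySeed = "integer",
    masterSeed = "integer"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (length(object@strataCounts) != 3L)
    msg <- c(msg, "strataCounts must have length 3")
  if (object@nTarget != sum(object@strataCounts))
    msg <- c(msg, "nTarget must equal sum(strataCounts)")
  if (object@mnfK > object@bands)
    msg <- c(msg, "mnfK must not exceed the number of bands")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})
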