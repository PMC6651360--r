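#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small generic accessors used throughout the package instead of direct
#' slot access.
#'
#' @param x An object of one of the package's classes.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("sceneDim", function(x) standardGeneric("sceneDim"))

#' @rdname accessors
#' @export
setGeneric("coverField", function(x) standardGeneric("coverField"))

#' @rdname accessors
#' @export
setGeneric("truthPatches", function(x) standardGeneric("truthPatches"))

#' @rdname accessors
#' @export
setGeneric("gsd", function(x) standardGeneric("gsd"))

#' @rdname accessors
#' @export
setGeneric("geotransform", function(x) standardGeneric("geotransform"))

#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("polygonMeta", function(x) standardGeneric("polygonMeta"))

#' @rdname accessors
#' @export
setGeneric("polygonPixels", function(x, id) standardGeneric("polygonPixels"))

#' @rdname accessors
#' @export
setGeneric("labelRaster", function(x) standardGeneric("labelRaster"))

#' @rdname accessors
#' @export
setGeneric("probRaster", function(x) standardGeneric("probRaster"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralLibrary", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("nBands", "HyperCube", function(x) dim(x@data)[3])

#' @rdname accessors
#' @export
setMethod("sceneDim", "HyperCube", function(x) dim(x@data)[1:2])

#' @rdname accessors
#' @export
setMethod("sceneDim", "CoverScene", function(x) dim(x@cover))

#' @rdname accessors
#' @export
setMethod("coverField", "CoverScene", function(x) x@cover)

#' @rdname accessors
#' @export
setMethod("truthPatches", "CoverScene", function(x) x@truthPatches)

#' @rdname accessors
#' @export
setMethod("gsd", "CoverScene", function(x) x@gsd)

#' @rdname accessors
#' @export
setMethod("gsd", "HyperCube", function(x) x@gsd)

#' @rdname accessors
#' @export
setMethod("gsd", "ClassifiedMap", function(x) x@gsd)

#' @rdname accessors
#' @export
setMethod("geotransform", "HyperCube", function(x) x@geotransform)

#' @rdname accessors
#' @export
setMethod("nodataMask", "HyperCube", function(x) x@nodataMask)

#' @rdname accessors
#' @export
setMethod("eigenvalues", "MNFResult", function(x) x@eigenvalues)

#' @rdname accessors
#' @export
setMethod("polygonMeta", "SampleDesign", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("polygonPixels", "SampleDesign", function(x, id) {
  if (!all(id %in% names(x@pixels))) stop("unknown polygon id")
  if (length(id) == 1L) x@pixels[[id]] else x@pixels[id]
})

#' @rdname accessors
#' @export
setMethod("labelRaster", "ClassifiedMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("probRaster", "ClassifiedMap", function(x) x@prob)

setMethod("show", "SpectralLibrary", function(object) {
  cat("SpectralLibrary:", nrow(object@spectra), "endmembers x",
      ncol(object@spectra), "bands\n")
  cat("  wavelengths:", min(object@wavelengths), "-",
      max(object@wavelengths), "nm\n")
  cat("  target endmember:", object@target, "\n")
})

setMethod("show", "CoverScene", function(object) {
  d <- dim(object@cover)
  cat("CoverScene:", d[1], "x", d[2], "pixels at", object@gsd, "m GSD\n")
  cat(sprintf("  prevalence (cover >= 0.2): %.4f\n", mean(object@cover >= 0.2)))
  cat("  truth patches:", length(object@truthPatches), "\n")
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat("HyperCube:", d[1], "x", d[2], "pixels,", d[3], "bands,",
      object@gsd, "m GSD\n")
  cat("  nodata pixels:", sum(object@nodataMask), "\n")
})

setMethod("show", "MNFResult", function(object) {
  cat("MNFResult:", length(object@eigenvalues), "components\n")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(object@eigenvalues, 5), 4), collapse = ", "),
      "...\n")
})

setMethod("show", "SampleDesign", function(object) {
  m <- object@meta
  cat("SampleDesign:", sum(m$klass == "target"), "target +",
      sum(m$klass == "background"), "background polygons (radius",
      object@radius, "m)\n")
  tg <- m[m$klass == "target", ]
  tab <- table(factor(tg$stratum, levels = c("20-40", "50-70", "80-100")))
  cat("  strata:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ClassifiedMap", function(object) {
  d <- dim(object@labels)
  valid <- !is.na(object@labels)
  cat("ClassifiedMap:", d[1], "x", d[2], "pixels\n")
  cat(sprintf("  target area: %.2f%% of %d valid pixels\n",
              100 * mean(object@labels[valid] == 1L), sum(valid)))
})

setMethod("show", "ConfusionAreas", function(object) {
  cat("ConfusionAreas (m^2): TP", object@tpArea, "FP", object@fpArea,
      "TN", object@tnArea, "FN", object@fnArea, "\n")
  if (!is.na(object@tpPct))
    cat("  percentages: TP", object@tpPct, "FP", object@fpPct,
        "TN", object@tnPct, "FN", object@fnPct, "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport [", object@scenario, "]\n", sep = "")
  cat(sprintf("  Kappa %.3f  F1 %.3f  map area %.2f%%\n",
              object@kappa, object@f1, object@mapAreaPct))
  cat("  stratum TP%:",
      paste(names(object@stratumTPPct),
            round(object@stratumTPPct, 1), sep = "=", collapse = ", "),
      " background FP%:", round(object@backgroundFPPct, 1), "\n")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec %s (stage %d): cover %d-%d%%, %d target + %d background training polygons\n",
              object@name, object@stage, object@coverRange[1],
              object@coverRange[2], object@nTargetTrain,
              object@nBackgroundTrain))
})
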