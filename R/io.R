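#' Write a cube in ENVI BSQ format
#'
#' Flat 32-bit float band-sequential binary plus a text header carrying
#' the dimensions, map info and wavelength list.
#'
#' @param cube A \linkS4class{HyperCube}.
#' @param path Output path of the binary file; the header is written to
#'   \code{paste0(path, ".hdr")}.
#' @return Invisibly, \code{path}.
#' @export
writeENVI <- function(cube, path) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    # ENVI stores each band line by line (row-major)
    writeBin(as.numeric(t(cube@data[, , b])), con, size = 4,
             endian = "little")
  }
  gt <- cube@geotransform
  hdr <- c(
    "ENVI",
    "description = {coverwise export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("map info = {Arbitrary, 1, 1, %.6f, %.6f, %.6f, %.6f}",
            gt[1], gt[4], gt[2], abs(gt[6])),
    paste0("wavelength = {",
           paste(format(cube@wavelengths, trim = TRUE), collapse = ", "),
           "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse an ENVI header into a named list.
parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getField <- function(name) {
    m <- regmatches(txt, regexec(
      paste0(name, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"), txt))[[1]]
    if (length(m) < 2) return(NULL)
    gsub("^\\{|\\}$", "", trimws(m[2]))
  }
  list(
    samples = as.integer(getField("samples")),
    lines = as.integer(getField("lines")),
    bands = as.integer(getField("bands")),
    dataType = as.integer(getField("data type")),
    interleave = tolower(getField("interleave")),
    wavelength = {
      w <- getField("wavelength")
      if (is.null(w)) NULL else as.numeric(strsplit(w, ",")[[1]])
    },
    mapInfo = {
      mi <- getField("map info")
      if (is.null(mi)) NULL else trimws(strsplit(mi, ",")[[1]])
    }
  )
}

#' Read an ENVI BSQ cube
#'
#' @param path Path of the binary file; the header is expected at
#'   \code{paste0(path, ".hdr")}.
#' @return A \linkS4class{HyperCube}.
#' @export
readENVI <- function(path) {
  h <- parseEnviHeader(paste0(path, ".hdr"))
  if (h$dataType != 4L || h$interleave != "bsq")
    stop("only float32 BSQ is supported")
  n <- h$samples * h$lines * h$bands
  raw <- readBin(path, numeric(), n = n, size = 4, endian = "little")
  arr <- array(NA_real_, dim = c(h$lines, h$samples, h$bands))
  per <- h$samples * h$lines
  for (b in seq_len(h$bands)) {
    arr[, , b] <- t(matrix(raw[((b - 1) * per + 1):(b * per)],
                           nrow = h$samples))
  }
  gsd <- if (!is.null(h$mapInfo)) as.numeric(h$mapInfo[6]) else 1
  x0 <- if (!is.null(h$mapInfo)) as.numeric(h$mapInfo[4]) else 0
  y0 <- if (!is.null(h$mapInfo)) as.numeric(h$mapInfo[5]) else h$lines * gsd
  wl <- if (is.null(h$wavelength)) as.numeric(seq_len(h$bands)) else h$wavelength
  new("HyperCube", data = arr, wavelengths = wl, gsd = gsd,
      geotransform = c(x0, gsd, 0, y0, 0, -gsd),
      nodataMask = matrix(FALSE, h$lines, h$samples))
}

# Square polygon ring of one pixel in map coordinates (closed).
pixelRing <- function(row, col, geotransform) {
  x0 <- geotransform[1] + (col - 1) * geotransform[2]
  x1 <- x0 + geotransform[2]
  yT <- geotransform[4] + (row - 1) * geotransform[6]
  yB <- yT + geotransform[6]
  list(c(x0, yT), c(x1, yT), c(x1, yB), c(x0, yB), c(x0, yT))
}

#' Write truth patches as GeoJSON
#'
#' Each patch becomes a MultiPolygon feature (one square per member
#' pixel) with an \code{area_m2} property.
#'
#' @param patches Truth patches from \code{\link{extractTruthPatches}}.
#' @param geotransform Length-6 geotransform.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTruthPatchesGeoJSON <- function(patches, geotransform, path) {
  features <- lapply(patches, function(p) {
    rings <- lapply(seq_len(nrow(p$pixels)), function(i) {
      list(pixelRing(p$pixels[i, 1], p$pixels[i, 2], geotransform))
    })
    list(
      type = "Feature",
      properties = list(id = p$id, area_m2 = p$areaM2),
      geometry = list(type = "MultiPolygon", coordinates = rings)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sample design as GeoJSON points plus a CSV attribute table
#'
#' Point features at the polygon centres with radius, class, cover,
#' stratum and role attributes.
#'
#' @param design A \linkS4class{SampleDesign}.
#' @param geojsonPath,csvPath Output paths (either may be NULL to skip).
#' @return Invisibly, the design's attribute table.
#' @export
writeSampleDesign <- function(design, geojsonPath = NULL, csvPath = NULL) {
  m <- polygonMeta(design)
  if (!is.null(geojsonPath)) {
    features <- lapply(seq_len(nrow(m)), function(i) {
      list(
        type = "Feature",
        properties = list(id = m$id[i], klass = m$klass[i],
                          cover_pct = m$coverPct[i],
                          stratum = m$stratum[i], role = m$role[i],
                          radius_m = design@radius),
        geometry = list(type = "Point",
                        coordinates = c(m$centerX[i], m$centerY[i]))
      )
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = features),
      geojsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvPath))
    utils::write.csv(m, csvPath, row.names = FALSE)
  invisible(m)
}

#' Published zonal confusion areas for four herbaceous target species
#'
#' Control-area zonal statistics from a published airborne mapping
#' campaign of four invasive/expansive herbs (FU Filipendula ulmaria,
#' MC Molinia caerulea, PA Phragmites australis, SG Solidago gigantea),
#' one row per classification run (Stage 0, the five Stage-1 cover-range
#' scenarios, and the three Stage-2 training-set sizes): control species
#' and background areas and the TP/FP/TN/FN areas in m^2, plus the
#' printed integer percentage columns. Used as worked-example input for
#' the percentage-convention arithmetic and the winner-selection logic.
#'
#' @return A data.frame.
#' @export
publishedZonalAreas <- function() {
  utils::read.csv(system.file("extdata", "published_zonal_areas.csv",
                              package = "coverwise"),
                  stringsAsFactors = FALSE)
}

#' Published per-criterion winner patterns
#'
#' The per-criterion winners (accuracy measures; correct-pixel analysis;
#' field-mapping compatibility) and the chosen overall scenario for each
#' species, for Stage 1 and Stage 2 of the same published campaign.
#'
#' @return A data.frame.
#' @export
publishedWinnerPatterns <- function() {
  utils::read.csv(system.file("extdata", "published_scenario_winners.csv",
                              package = "coverwise"),
                  stringsAsFactors = FALSE)
}
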