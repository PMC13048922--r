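## Raster, table and model serialisation.
##
## Rasters are written as multi-page 32-bit float TIFF (one file per
## acquisition date; pages in band order BLUE, GREEN, RED, NIR, SWIR1, then
## the quality code scaled by 1/10) with a YAML sidecar recording the
## geotransform, band order, quality encoding and generating configuration.

gridFromColumn <- function(vals, gridRows, gridCols) {
  matrix(vals, gridRows, gridCols, byrow = TRUE)   # row-major unflatten
}

#' Write a scene's rasters and waypoint-ready metadata
#'
#' One multi-page float TIFF per acquisition date (bands then quality/10),
#' plus `truth.tif` and `strata.tif` (values scaled by 1/255) and a
#' `scene.yaml` sidecar with the geotransform and full configuration.
#'
#' @param scene a [SyntheticScene-class]
#' @param dir output directory (created if needed)
#' @return the sidecar path, invisibly
#' @export
writeSceneRasters <- function(scene, dir) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cube <- reflectanceCube(scene)
  gd <- gridDims(cube)
  dates <- acquisitionDates(cube)
  q <- qualityMatrix(cube)
  for (j in seq_along(dates)) {
    pages <- lapply(BAND_NAMES, function(b) {
      col <- bandMatrix(cube, b)[, j]
      col[is.na(col)] <- 0           # nodata filled; quality page flags it
      gridFromColumn(col, gd["rows"], gd["cols"])
    })
    pages <- c(pages, list(gridFromColumn(q[, j] / 10, gd["rows"], gd["cols"])))
    tiff::writeTIFF(pages, file.path(dir, paste0(format(dates[j]), ".tif")),
                    bits.per.sample = 32L)
  }
  tiff::writeTIFF(truthLabels(scene) / 255, file.path(dir, "truth.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(strataMap(scene) / 255, file.path(dir, "strata.tif"),
                  bits.per.sample = 32L)
  cfg <- scene@config
  sidecar <- list(
    format = "phenocube-scene-1",
    bands = as.list(BAND_NAMES),
    quality_page = "band 6; code = value * 10 (0 valid, 1 cloud, 2 nodata)",
    geo = geoMeta(cube),
    grid = list(rows = unname(gd["rows"]), cols = unname(gd["cols"])),
    dates = lapply(dates, format),
    config = list(gridRows = cfg@gridRows, gridCols = cfg@gridCols,
                  startDate = format(cfg@startDate),
                  endDate = format(cfg@endDate),
                  revisitDays = cfg@revisitDays, dropoutProb = cfg@dropoutProb,
                  cloudBetaParams = cfg@cloudBetaParams, gapProb = cfg@gapProb,
                  noiseSd = cfg@noiseSd, noiseType = cfg@noiseType,
                  rainRatePerYear = cfg@rainRatePerYear,
                  rainMagnitudeMean = cfg@rainMagnitudeMean,
                  nFires = cfg@nFires, pixelSize = cfg@pixelSize,
                  seed = cfg@seed))
  path <- file.path(dir, "scene.yaml")
  yaml::write_yaml(sidecar, path)
  invisible(path)
}

#' Read a reflectance cube from a raster directory
#'
#' Reconstructs a [ReflectanceCube-class] from the multi-page TIFFs and
#' `scene.yaml` sidecar written by [writeSceneRasters()].
#'
#' @param dir directory containing the rasters and sidecar
#' @return a [ReflectanceCube-class]
#' @export
readReflectanceCube <- function(dir) {
  sidecar <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  dates <- as.Date(unlist(sidecar$dates))
  gr <- sidecar$grid$rows; gc <- sidecar$grid$cols
  np <- gr * gc
  bands <- lapply(setNames(BAND_NAMES, BAND_NAMES), function(b)
    matrix(NA_real_, np, length(dates)))
  quality <- matrix(QUALITY_NODATA, np, length(dates))
  for (j in seq_along(dates)) {
    pages <- tiff::readTIFF(file.path(dir, paste0(format(dates[j]), ".tif")),
                            all = TRUE)
    qj <- as.integer(round(as.vector(t(pages[[6]])) * 10))
    quality[, j] <- qj
    for (b in seq_along(BAND_NAMES)) {
      v <- as.vector(t(pages[[b]]))
      v[qj == QUALITY_NODATA] <- NA_real_
      bands[[BAND_NAMES[b]]][, j] <- v
    }
  }
  pidx <- pixelIndexFrame(gr, gc)
  se <- SummarizedExperiment(
    assays = c(bands, list(quality = quality)),
    rowData = DataFrame(pixel_row = pidx$row, pixel_col = pidx$col),
    colData = DataFrame(date = dates))
  metadata(se) <- list(gridRows = gr, gridCols = gc, geo = sidecar$geo)
  new("ReflectanceCube", se)
}

#' Write / read waypoints as CSV
#'
#' Columns x, y, label, stratum — coordinates in the raster's geotransform
#' units, labels "buffel"/"buffel_free".
#'
#' @param waypoints data.frame from [sampleWaypoints()]
#' @param path CSV path
#' @return `readWaypointsCsv` returns the waypoint data.frame
#' @export
writeWaypointsCsv <- function(waypoints, path) {
  write.csv(waypoints[, intersect(c("x", "y", "label", "stratum"),
                                  names(waypoints))],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWaypointsCsv
#' @export
readWaypointsCsv <- function(path) read.csv(path)

#' Serialise a logistic model as JSON
#'
#' Intercept, named coefficients, selection order, BIC trajectory and fit
#' metadata, as a human-readable JSON document.
#'
#' @param model a [LogisticMapModel-class]
#' @param path JSON path
#' @return `readLogisticModelJson` returns the model
#' @export
writeLogisticModelJson <- function(model, path) {
  stopifnot(is(model, "LogisticMapModel"))
  doc <- list(intercept = model@intercept,
              coefficients = as.list(model@coefficients),
              selected_features = model@selectedFeatures,
              candidate_features = model@candidateFeatures,
              bic_path = model@bicPath,
              metadata = model@metadata[setdiff(names(model@metadata),
                                                "per_boot")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeLogisticModelJson
#' @export
readLogisticModelJson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(doc$coefficients)
  if (is.null(coefs)) coefs <- setNames(numeric(0), character(0))
  new("LogisticMapModel", intercept = doc$intercept, coefficients = coefs,
      selectedFeatures = as.character(doc$selected_features),
      candidateFeatures = as.character(doc$candidate_features),
      bicPath = doc$bic_path,
      metadata = as.list(doc$metadata))
}

#' Write a feature table as columnar CSV
#'
#' Columns pixel_row, pixel_col, then the named feature columns.
#'
#' @param table a [FeatureTable-class]
#' @param path CSV path
#' @export
writeFeatureTableCsv <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  write.csv(cbind(pixelIndex(table), as.data.frame(featureMatrix(table))),
            path, row.names = FALSE)
  invisible(path)
}

#' Write decomposition summaries as CSV
#'
#' One row per index and component: singular value and variance fraction.
#'
#' @param results named list of [DecompositionResult-class]
#' @param path CSV path
#' @export
writeDecompositionSummaryCsv <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(index = indexName(r),
               component = seq_along(singularValues(r)),
               singular_value = singularValues(r),
               variance_fraction = varianceFractions(r))))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a probability or occurrence grid as float TIFF
#'
#' Single-page 32-bit float TIFF plus a YAML sidecar with the geotransform.
#'
#' @param surface a [ProbabilitySurface-class] or numeric/integer grid matrix
#' @param path TIFF path
#' @param geo geotransform list (taken from the surface when omitted)
#' @export
writeSurfaceTiff <- function(surface, path, geo = NULL) {
  if (is(surface, "ProbabilitySurface")) {
    grid <- probabilityGrid(surface)
    if (is.null(geo)) geo <- geoMeta(surface)
  } else {
    grid <- surface
  }
  tiff::writeTIFF(clip01(grid), path, bits.per.sample = 32L)
  if (!is.null(geo))
    yaml::write_yaml(list(geo = geo), paste0(path, ".yaml"))
  invisible(path)
}
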