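## Mosaic quality control, vegetation indices, and the spatiotemporal matrix.

#' Per-date mosaic quality
#'
#' For each acquisition date, the fraction of pixels flagged as cloud and the
#' fraction carrying data (non-null). Cloudy pixels count as data for the
#' valid fraction: cloud and nodata are filtered on separate rules.
#'
#' @param cube a [ReflectanceCube-class]
#' @return data.frame with columns date, cloud_fraction, valid_fraction
#' @export
assessQuality <- function(cube) {
  stopifnot(is(cube, "ReflectanceCube"))
  q <- qualityMatrix(cube)
  if (ncol(q) == 0L) stop("cube has no acquisition dates", call. = FALSE)
  data.frame(date = acquisitionDates(cube),
             cloud_fraction = colMeans(q == QUALITY_CLOUD),
             valid_fraction = colMeans(q != QUALITY_NODATA))
}

#' Filter mosaics on cloud cover and data completeness
#'
#' Retains dates with cloud fraction strictly below `cloudMax` and valid
#' fraction strictly above `validMin` (the "less than 3% cloud" / "more than
#' 90% non-null" rules read strictly, so boundary dates are excluded). Input
#' order is preserved; the filter is idempotent.
#'
#' @param quality data.frame from [assessQuality()]
#' @param cloudMax maximum tolerated cloud fraction (exclusive), default 0.03
#' @param validMin minimum required valid fraction (exclusive), default 0.90
#' @return the retained rows' dates, in input order
#' @export
filterMosaics <- function(quality, cloudMax = 0.03, validMin = 0.90) {
  stopifnot_scalar(cloudMax, "cloudMax", min = 0, max = 1)
  stopifnot_scalar(validMin, "validMin", min = 0, max = 1)
  keep <- quality$cloud_fraction < cloudMax & quality$valid_fraction > validMin
  if (!any(keep))
    stop("no mosaics pass the quality filter; consider relaxing cloudMax/validMin",
         call. = FALSE)
  quality$date[keep]
}

## Table of index formulas over named band matrices. EVI constants:
## gain G = 2.5, aerosol coefficients C1 = 6, C2 = 7.5, soil adjustment L = 1.
EVI_CONSTANTS <- c(G = 2.5, C1 = 6, C2 = 7.5, L = 1)

indexFormula <- function(name, bands, constants = EVI_CONSTANTS) {
  safeRatio <- function(num, den) {
    out <- num / den
    out[abs(den) < 1e-12] <- NA_real_  # zero denominators become missing
    out
  }
  switch(name,
    EVI = safeRatio(constants[["G"]] * (bands$NIR - bands$RED),
                    bands$NIR + constants[["C1"]] * bands$RED -
                      constants[["C2"]] * bands$BLUE + constants[["L"]]),
    NBR = safeRatio(bands$NIR - bands$SWIR1, bands$NIR + bands$SWIR1),
    NDVI = safeRatio(bands$NIR - bands$RED, bands$NIR + bands$RED),
    NDWI = safeRatio(bands$GREEN - bands$NIR, bands$GREEN + bands$NIR),
    stop(sprintf("unknown vegetation index '%s'", name), call. = FALSE))
}

requiredBands <- function(name) {
  switch(name,
    EVI = c("BLUE", "RED", "NIR"),
    NBR = c("NIR", "SWIR1"),
    NDVI = c("RED", "NIR"),
    NDWI = c("GREEN", "NIR"),
    stop(sprintf("unknown vegetation index '%s'", name), call. = FALSE))
}

#' Compute a vegetation index over a cube
#'
#' Applies the index formula per pixel and date. Cloud and nodata pixels
#' propagate as missing; zero denominators yield missing values, never
#' infinities. EVI uses gain G = 2.5 and coefficients C1 = 6, C2 = 7.5,
#' L = 1 unless overridden.
#'
#' @param cube a [ReflectanceCube-class]
#' @param index one of "EVI", "NBR", "NDVI", "NDWI"
#' @param constants named EVI constants (G, C1, C2, L)
#' @return pixels x dates numeric matrix with NA where invalid
#' @examples
#' # NDVI of NIR = 0.4, RED = 0.1 is 0.3 / 0.5 = 0.6
#' @export
computeIndex <- function(cube, index, constants = EVI_CONSTANTS) {
  stopifnot(is(cube, "ReflectanceCube"))
  index <- match.arg(toupper(index), INDEX_NAMES)
  need <- requiredBands(index)
  missingBand <- setdiff(need, assayNames(cube))
  if (length(missingBand))
    stop(sprintf("band %s required by index %s is missing",
                 missingBand[1], index), call. = FALSE)
  bands <- lapply(setNames(BAND_NAMES, BAND_NAMES), function(b)
    if (b %in% assayNames(cube)) assay(cube, b) else NULL)
  vals <- indexFormula(index, bands, constants)
  vals[qualityMatrix(cube) != QUALITY_VALID] <- NA_real_
  vals
}

#' Assemble the dates-by-pixels spatiotemporal matrix
#'
#' Subsets an index's pixel x date values to the retained dates, transposes
#' to rows = dates / columns = pixels (row-major pixel flattening from the
#' grid's top-left), and fills residual missing entries. The default policy
#' interpolates each pixel's time series linearly between its valid
#' observations, extending the ends with the nearest valid value; "mean"
#' fills with the pixel's mean instead. The imputed-entry count is recorded.
#'
#' @param indexValues pixels x dates matrix from [computeIndex()]
#' @param cube the source [ReflectanceCube-class] (dates, grid, geo)
#' @param retainedDates Date vector from [filterMosaics()] (>= 2 dates)
#' @param indexName name stored with the matrix
#' @param imputePolicy "linear" (default) or "mean"
#' @return a [SpatioTemporalMatrix-class]
#' @export
buildMatrix <- function(indexValues, cube, retainedDates, indexName,
                        imputePolicy = c("linear", "mean")) {
  imputePolicy <- match.arg(imputePolicy)
  stopifnot(is(cube, "ReflectanceCube"))
  allDates <- acquisitionDates(cube)
  sel <- match(as.Date(retainedDates), allDates)
  if (anyNA(sel)) stop("retainedDates must be a subset of the cube's dates",
                       call. = FALSE)
  if (length(sel) < 2L)
    stop("at least two retained dates are required", call. = FALSE)
  M <- t(indexValues[, sel, drop = FALSE])          # dates x pixels
  gd <- gridDims(cube)
  pidx <- pixelIndexFrame(gd["rows"], gd["cols"])

  nMissing <- sum(is.na(M))
  if (nMissing > 0) {
    tNum <- as.numeric(as.Date(retainedDates))
    bad <- which(colSums(!is.na(M)) == 0L)
    if (length(bad)) {
      coords <- paste(sprintf("(%d,%d)", pidx$row[bad], pidx$col[bad]),
                      collapse = ", ")
      stop(sprintf("pixels with no valid observations: %s", coords),
           call. = FALSE)
    }
    needsFill <- which(colSums(is.na(M)) > 0L)
    for (j in needsFill) {
      ok <- !is.na(M[, j])
      M[, j] <- if (imputePolicy == "linear" && sum(ok) > 1L) {
        approx(tNum[ok], M[ok, j], xout = tNum, rule = 2)$y
      } else {
        ifelse(ok, M[, j], mean(M[ok, j]))
      }
    }
  }
  new("SpatioTemporalMatrix", values = unname(M),
      dates = as.Date(retainedDates), pixelIndex = pidx,
      indexName = indexName, nImputed = as.integer(nMissing),
      geo = geoMeta(cube), gridRows = as.integer(gd["rows"]),
      gridCols = as.integer(gd["cols"]))
}

#' One call from cube to index matrices
#'
#' Convenience wrapper: quality assessment, mosaic filtering and matrix
#' construction for each requested index.
#'
#' @param cube a [ReflectanceCube-class]
#' @param indices character vector of index names
#' @param cloudMax,validMin filter thresholds (see [filterMosaics()])
#' @param imputePolicy passed to [buildMatrix()]
#' @return named list of [SpatioTemporalMatrix-class] objects
#' @export
buildIndexMatrices <- function(cube, indices = INDEX_NAMES, cloudMax = 0.03,
                               validMin = 0.90, imputePolicy = "linear") {
  qual <- assessQuality(cube)
  retained <- filterMosaics(qual, cloudMax, validMin)
  out <- lapply(setNames(indices, tolower(indices)), function(idx)
    buildMatrix(computeIndex(cube, idx), cube, retained, toupper(idx),
                imputePolicy))
  out
}
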