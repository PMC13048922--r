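## Accessor and show methods. Bioconductor convention: user code touches
## slots only through these.

#' @rdname phenocube-generics
#' @aliases gridDims,ReflectanceCube-method
setMethod("gridDims", "ReflectanceCube", function(object) {
  md <- metadata(object)
  c(rows = md$gridRows, cols = md$gridCols)
})

#' @rdname phenocube-generics
setMethod("acquisitionDates", "ReflectanceCube", function(object)
  as.Date(colData(object)$date))

#' @rdname phenocube-generics
setMethod("bandMatrix", "ReflectanceCube", function(object, band) {
  if (!band %in% BAND_NAMES)
    stop(sprintf("unknown band '%s'", band), call. = FALSE)
  assay(object, band)
})

#' @rdname phenocube-generics
setMethod("qualityMatrix", "ReflectanceCube", function(object)
  assay(object, "quality"))

#' @rdname phenocube-generics
setMethod("validMask", "ReflectanceCube", function(object)
  assay(object, "quality") == QUALITY_VALID)

#' @rdname phenocube-generics
setMethod("geoMeta", "ReflectanceCube", function(object) metadata(object)$geo)

setMethod("show", "ReflectanceCube", function(object) {
  gd <- gridDims(object)
  d <- acquisitionDates(object)
  cat(sprintf("ReflectanceCube: %d x %d pixels, %d acquisition dates (%s .. %s)\n",
              gd["rows"], gd["cols"], length(d), min(d), max(d)))
  q <- qualityMatrix(object)
  cat(sprintf("  bands: %s | valid %.1f%%, cloud %.1f%%, nodata %.1f%%\n",
              paste(BAND_NAMES, collapse = ","),
              100 * mean(q == QUALITY_VALID), 100 * mean(q == QUALITY_CLOUD),
              100 * mean(q == QUALITY_NODATA)))
})

#' @rdname phenocube-generics
setMethod("reflectanceCube", "SyntheticScene", function(object) object@cube)

#' @rdname phenocube-generics
setMethod("truthLabels", "SyntheticScene", function(object) object@truth)

#' @rdname phenocube-generics
setMethod("strataMap", "SyntheticScene", function(object) object@strata)

#' @rdname phenocube-generics
setMethod("coverMap", "SyntheticScene", function(object) object@cover)

#' @rdname phenocube-generics
setMethod("rainfallSeries", "SyntheticScene", function(object) object@rainfall)

#' @rdname phenocube-generics
setMethod("fireSchedule", "SyntheticScene", function(object) object@fire)

#' @rdname phenocube-generics
setMethod("gridDims", "SyntheticScene", function(object)
  c(rows = object@config@gridRows, cols = object@config@gridCols))

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene\n")
  show(object@cube)
  cat(sprintf("  buffel prevalence %.1f%%; %d strata; %d rain events; %d fires\n",
              100 * mean(object@truth == 1L), length(unique(as.vector(object@strata))),
              length(object@rainfall@times), length(object@fire@events)))
})

#' @rdname phenocube-generics
setMethod("matrixValues", "SpatioTemporalMatrix", function(object) object@values)

#' @rdname phenocube-generics
setMethod("acquisitionDates", "SpatioTemporalMatrix", function(object) object@dates)

#' @rdname phenocube-generics
setMethod("pixelIndex", "SpatioTemporalMatrix", function(object) object@pixelIndex)

#' @rdname phenocube-generics
setMethod("indexName", "SpatioTemporalMatrix", function(object) object@indexName)

#' @rdname phenocube-generics
setMethod("gridDims", "SpatioTemporalMatrix", function(object)
  c(rows = object@gridRows, cols = object@gridCols))

setMethod("show", "SpatioTemporalMatrix", function(object) {
  cat(sprintf("SpatioTemporalMatrix [%s]: %d dates x %d pixels (%d imputed entries)\n",
              object@indexName, nrow(object@values), ncol(object@values),
              object@nImputed))
})

#' @rdname phenocube-generics
setMethod("singularValues", "DecompositionResult", function(object)
  object@singularValues)

#' @rdname phenocube-generics
setMethod("temporalModes", "DecompositionResult", function(object)
  object@temporalModes)

#' @rdname phenocube-generics
setMethod("spatialLoadings", "DecompositionResult", function(object)
  object@spatialLoadings)

#' @rdname phenocube-generics
setMethod("varianceFractions", "DecompositionResult", function(object)
  object@varianceFractions)

#' @rdname phenocube-generics
setMethod("indexName", "DecompositionResult", function(object) object@indexName)

setMethod("show", "DecompositionResult", function(object) {
  k <- length(object@singularValues)
  cat(sprintf("DecompositionResult [%s, %s]: rank-%d, cumulative variance %.1f%%\n",
              object@indexName, object@method, k,
              100 * sum(object@varianceFractions)))
})

#' @rdname phenocube-generics
setMethod("featureMatrix", "FeatureTable", function(object) object@values)

#' @rdname phenocube-generics
setMethod("pixelIndex", "FeatureTable", function(object) object@pixelIndex)

#' @rdname phenocube-generics
setMethod("gridDims", "FeatureTable", function(object)
  c(rows = object@gridRows, cols = object@gridCols))

#' @rdname phenocube-generics
setMethod("geoMeta", "FeatureTable", function(object) object@geo)

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d pixels x %d features (%s; k = %d)\n",
              nrow(object@values), ncol(object@values),
              paste(object@indices, collapse = ","), object@retainedK))
})

#' @rdname phenocube-generics
setMethod("selectedFeatures", "LogisticMapModel", function(object)
  object@selectedFeatures)

#' @importFrom stats coef
#' @export
setMethod("coef", "LogisticMapModel", function(object, ...)
  c("(Intercept)" = object@intercept, object@coefficients))

setMethod("show", "LogisticMapModel", function(object) {
  cat(sprintf("LogisticMapModel: intercept %.4g, %d selected of %d candidates\n",
              object@intercept, length(object@selectedFeatures),
              length(object@candidateFeatures)))
  if (length(object@selectedFeatures))
    cat("  ", paste(sprintf("%s = %.4g", object@selectedFeatures,
                            object@coefficients), collapse = ", "), "\n")
  cat(sprintf("  BIC: %.2f -> %.2f over %d steps\n",
              object@bicPath[1], tail(object@bicPath, 1),
              length(object@bicPath) - 1L))
})

setMethod("show", "NeuralNetModel", function(object) {
  cat(sprintf("NeuralNetModel: %d -> %d (tanh) -> 1 (sigmoid); converged = %s\n",
              nrow(object@W1), ncol(object@W1),
              isTRUE(object@metadata$converged)))
})

#' @rdname phenocube-generics
setMethod("probabilityGrid", "ProbabilitySurface", function(object) object@prob)

#' @rdname phenocube-generics
setMethod("geoMeta", "ProbabilitySurface", function(object) object@geo)

setMethod("show", "ProbabilitySurface", function(object) {
  cat(sprintf("ProbabilitySurface [%s]: %d x %d, P in [%.3f, %.3f], mean %.3f\n",
              object@modelId, nrow(object@prob), ncol(object@prob),
              min(object@prob), max(object@prob), mean(object@prob)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%s): %d bootstraps, train fraction %.3f\n",
              if (is.null(object@metadata$model)) "model" else object@metadata$model,
              object@nBoot, object@trainFraction))
  m <- object@metrics
  for (role in unique(m$role)) {
    sub <- m[m$role == role, ]
    cat(sprintf("  %-10s %s\n", role,
                paste(sprintf("%s %.3f+/-%.3f", sub$metric, sub$mean, sub$se),
                      collapse = "  ")))
  }
})

setMethod("show", "RainfallSeries", function(object) {
  cat(sprintf("RainfallSeries: %d events from %s (mean magnitude %.2f)\n",
              length(object@times), object@origin,
              if (length(object@magnitudes)) mean(object@magnitudes) else NA))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %dx%d px, %s..%s, revisit %g d, dropout %.2f, seed %d\n",
              object@gridRows, object@gridCols, object@startDate, object@endDate,
              object@revisitDays, object@dropoutProb, object@seed))
})

#' Event dates of a rainfall series
#' @param object a [RainfallSeries-class]
#' @return Date vector of (whole-day) event dates
#' @export
eventDates <- function(object) {
  stopifnot(is(object, "RainfallSeries"))
  object@origin + floor(object@times)
}

#' Event magnitudes of a rainfall series
#' @param object a [RainfallSeries-class]
#' @return numeric vector of magnitudes
#' @export
eventMagnitudes <- function(object) {
  stopifnot(is(object, "RainfallSeries"))
  object@magnitudes
}
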