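#' @name phenocube-generics
#' @title Accessor generics
#' @description Accessor generics for the package's S4 containers. Slot access
#'   from user code should always go through these.
#' @param object an S4 object from this package
#' @param ... passed to methods
NULL

#' @rdname phenocube-generics
#' @export
setGeneric("gridDims", function(object) standardGeneric("gridDims"))

#' @rdname phenocube-generics
#' @export
setGeneric("acquisitionDates", function(object) standardGeneric("acquisitionDates"))

#' @rdname phenocube-generics
#' @param band band name (BLUE, GREEN, RED, NIR, SWIR1)
#' @export
setGeneric("bandMatrix", function(object, band) standardGeneric("bandMatrix"))

#' @rdname phenocube-generics
#' @export
setGeneric("qualityMatrix", function(object) standardGeneric("qualityMatrix"))

#' @rdname phenocube-generics
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname phenocube-generics
#' @export
setGeneric("geoMeta", function(object) standardGeneric("geoMeta"))

#' @rdname phenocube-generics
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @rdname phenocube-generics
#' @export
setGeneric("strataMap", function(object) standardGeneric("strataMap"))

#' @rdname phenocube-generics
#' @export
setGeneric("coverMap", function(object) standardGeneric("coverMap"))

#' @rdname phenocube-generics
#' @export
setGeneric("reflectanceCube", function(object) standardGeneric("reflectanceCube"))

#' @rdname phenocube-generics
#' @export
setGeneric("rainfallSeries", function(object) standardGeneric("rainfallSeries"))

#' @rdname phenocube-generics
#' @export
setGeneric("fireSchedule", function(object) standardGeneric("fireSchedule"))

#' @rdname phenocube-generics
#' @export
setGeneric("matrixValues", function(object) standardGeneric("matrixValues"))

#' @rdname phenocube-generics
#' @export
setGeneric("pixelIndex", function(object) standardGeneric("pixelIndex"))

#' @rdname phenocube-generics
#' @export
setGeneric("indexName", function(object) standardGeneric("indexName"))

#' @rdname phenocube-generics
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname phenocube-generics
#' @export
setGeneric("temporalModes", function(object) standardGeneric("temporalModes"))

#' @rdname phenocube-generics
#' @export
setGeneric("spatialLoadings", function(object) standardGeneric("spatialLoadings"))

#' @rdname phenocube-generics
#' @export
setGeneric("varianceFractions", function(object) standardGeneric("varianceFractions"))

#' @rdname phenocube-generics
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname phenocube-generics
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname phenocube-generics
#' @export
setGeneric("probabilityGrid", function(object) standardGeneric("probabilityGrid"))

#' Score class-membership probabilities
#'
#' Returns P(buffel) for each row of a feature matrix under a fitted model.
#' Both model classes (logistic and neural net) implement this generic, so
#' evaluation code is model-agnostic.
#'
#' @param model a fitted [LogisticMapModel-class] or [NeuralNetModel-class]
#' @param features numeric matrix with named columns covering the model's
#'   required features
#' @param ... passed to methods
#' @return numeric vector of probabilities in \[0,1\]
#' @export
setGeneric("scoreProbability", function(model, features, ...)
  standardGeneric("scoreProbability"))
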