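#' Phenological response parameters for a cover class
#'
#' Describes how the fractional green cover of one vegetation class responds
#' to a rainfall pulse: after a lag, greenness rises linearly at `riseRate`
#' per day to its peak and then decays exponentially with half-life
#' `decayHalflifeDays`. `amplitude` scales the peak response per unit rainfall
#' magnitude; `baseline` is the dry-season green fraction.
#'
#' @slot lagDays response delay after rain (days)
#' @slot riseRate green-up rate per day once the lag has elapsed
#' @slot decayHalflifeDays senescence half-life (days)
#' @slot amplitude peak fractional green cover per unit rainfall magnitude
#' @slot baseline dry-season fractional green cover
#' @export
setClass("PhenologyParams",
  representation(lagDays = "numeric", riseRate = "numeric",
                 decayHalflifeDays = "numeric", amplitude = "numeric",
                 baseline = "numeric"),
  validity = function(object) {
    v <- c(lagDays = object@lagDays, riseRate = object@riseRate,
           decayHalflifeDays = object@decayHalflifeDays,
           amplitude = object@amplitude, baseline = object@baseline)
    if (any(!is.finite(v)) || any(v < 0))
      return("all phenology parameters must be finite and nonnegative")
    TRUE
  })

#' @rdname PhenologyParams-class
#' @param lagDays,riseRate,decayHalflifeDays,amplitude,baseline see slots
#' @return a `PhenologyParams` object
#' @export
PhenologyParams <- function(lagDays, riseRate, decayHalflifeDays, amplitude,
                            baseline) {
  new("PhenologyParams", lagDays = lagDays, riseRate = riseRate,
      decayHalflifeDays = decayHalflifeDays, amplitude = amplitude,
      baseline = baseline)
}

COVER_CLASS_NAMES <- c("buffel", "native_tussock", "spinifex", "shrub_canopy",
                       "bare", "riparian_woodland")

#' A simulated land-cover class
#'
#' Bundles a class name, its phenological response and a 5-band vegetation
#' endmember (BLUE, GREEN, RED, NIR, SWIR1 surface reflectance in \[0,1\]).
#' The class set is closed: names must come from the simulator's enumeration
#' (buffel, native_tussock, spinifex, shrub_canopy, bare, riparian_woodland).
#'
#' @slot name class name (one of the closed enumeration)
#' @slot phenology a [PhenologyParams-class]
#' @slot endmember named numeric length-5 reflectance vector
#' @export
setClass("CoverClass",
  representation(name = "character", phenology = "PhenologyParams",
                 endmember = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !(object@name %in% COVER_CLASS_NAMES))
      return(sprintf("class name must be one of: %s",
                     paste(COVER_CLASS_NAMES, collapse = ", ")))
    if (length(object@endmember) != 5L ||
        !identical(names(object@endmember), BAND_NAMES))
      return("endmember must be a length-5 vector named BLUE, GREEN, RED, NIR, SWIR1")
    if (any(object@endmember < 0 | object@endmember > 1))
      return("endmember reflectances must lie in [0, 1]")
    TRUE
  })

#' @rdname CoverClass-class
#' @param name,phenology,endmember see slots
#' @export
CoverClass <- function(name, phenology, endmember) {
  new("CoverClass", name = name, phenology = phenology, endmember = endmember)
}

#' Configuration of a synthetic scene
#'
#' Fixes every free parameter of the synthetic-scene generator: grid size,
#' acquisition calendar, data dropout, cloud regime, reflectance noise, the
#' rainfall and fire processes, and the master seed. The same config plus the
#' same seed yields a bit-identical scene.
#'
#' @slot gridRows,gridCols pixel counts (>= 1)
#' @slot startDate,endDate calendar span of acquisitions
#' @slot revisitDays nominal revisit interval (days)
#' @slot dropoutProb fraction of nominal acquisitions lost, in \[0, 1)
#' @slot cloudBetaParams shape1/shape2 of the Beta per-date cloud fraction
#' @slot gapProb probability a date carries a nodata swath gap
#' @slot noiseSd reflectance noise standard deviation (>= 0)
#' @slot noiseType "additive" or "multiplicative"
#' @slot rainRatePerYear Poisson rainfall-event rate (events / year)
#' @slot rainMagnitudeMean mean of exponential event magnitudes
#' @slot nFires number of fire events over the span
#' @slot pixelSize ground pixel size in metres
#' @slot seed integer master seed
#' @export
setClass("SceneConfig",
  representation(gridRows = "integer", gridCols = "integer",
                 startDate = "Date", endDate = "Date",
                 revisitDays = "numeric", dropoutProb = "numeric",
                 cloudBetaParams = "numeric", gapProb = "numeric",
                 noiseSd = "numeric", noiseType = "character",
                 rainRatePerYear = "numeric", rainMagnitudeMean = "numeric",
                 nFires = "integer", pixelSize = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@gridRows < 1L || object@gridCols < 1L)
      return("grid dimensions must be >= 1")
    if (object@startDate >= object@endDate)
      return("startDate must precede endDate")
    if (object@revisitDays <= 0)
      return("revisitDays must be positive")
    if (object@dropoutProb < 0 || object@dropoutProb >= 1)
      return("dropoutProb must lie in [0, 1)")
    if (length(object@cloudBetaParams) != 2L || any(object@cloudBetaParams <= 0))
      return("cloudBetaParams must be two positive Beta shape parameters")
    if (object@gapProb < 0 || object@gapProb > 1)
      return("gapProb must lie in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (!(object@noiseType %in% c("additive", "multiplicative")))
      return("noiseType must be 'additive' or 'multiplicative'")
    if (object@rainRatePerYear <= 0) return("rainRatePerYear must be positive")
    if (object@rainMagnitudeMean <= 0) return("rainMagnitudeMean must be positive")
    if (object@nFires < 0L) return("nFires must be >= 0")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  })

#' A rainfall-pulse event series
#'
#' Event times are continuous day offsets from `origin`, strictly increasing;
#' magnitudes are nonnegative rainfall-depth equivalents.
#'
#' @slot origin Date the offsets are measured from
#' @slot times numeric day offsets, strictly increasing
#' @slot magnitudes nonnegative event magnitudes
#' @export
setClass("RainfallSeries",
  representation(origin = "Date", times = "numeric", magnitudes = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@magnitudes))
      return("times and magnitudes must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      return("event times must be strictly increasing")
    if (any(object@magnitudes < 0))
      return("event magnitudes must be >= 0")
    TRUE
  })

#' A schedule of fire events
#'
#' Each event is a list with `time` (day offset from `origin`), `mask`
#' (logical burned-pixel matrix conforming to the scene grid) and `severity`
#' in \[0,1\].
#'
#' @slot origin Date reference
#' @slot events list of fire events
#' @export
setClass("FireSchedule",
  representation(origin = "Date", events = "list"),
  validity = function(object) {
    for (ev in object@events) {
      if (!all(c("time", "mask", "severity") %in% names(ev)))
        return("each fire event needs 'time', 'mask' and 'severity'")
      if (!is.logical(ev$mask) || !is.matrix(ev$mask))
        return("fire masks must be logical matrices")
      if (ev$severity < 0 || ev$severity > 1)
        return("fire severity must lie in [0, 1]")
    }
    TRUE
  })

#' Dated multiband reflectance cube
#'
#' A [SummarizedExperiment-class] with rows = pixels (row-major from the
#' top-left of the grid) and columns = acquisition dates. Assays are the five
#' reflectance bands (BLUE, GREEN, RED, NIR, SWIR1, each in \[0,1\] where
#' valid) plus an integer "quality" code (0 = valid, 1 = cloud, 2 = nodata).
#' `rowData` carries `pixel_row`/`pixel_col`; `colData` carries `date`;
#' `metadata` carries the grid dimensions and the geotransform.
#'
#' @export
setClass("ReflectanceCube", contains = "SummarizedExperiment",
  validity = function(object) {
    need <- c(BAND_NAMES, "quality")
    if (!all(need %in% assayNames(object)))
      return(sprintf("missing assays: %s",
                     paste(setdiff(need, assayNames(object)), collapse = ", ")))
    if (is.null(colData(object)$date))
      return("colData must carry acquisition dates in column 'date'")
    d <- as.numeric(colData(object)$date)
    if (length(d) > 1 && any(diff(d) <= 0))
      return("acquisition dates must be strictly increasing")
    md <- metadata(object)
    if (is.null(md$gridRows) || is.null(md$gridCols) || is.null(md$geo))
      return("metadata must carry gridRows, gridCols and geo")
    if (nrow(object) != md$gridRows * md$gridCols)
      return("pixel count must equal gridRows * gridCols")
    q <- assay(object, "quality")
    for (b in BAND_NAMES) {
      v <- assay(object, b)[q == QUALITY_VALID]
      if (length(v) && (anyNA(v) || any(v < 0 | v > 1)))
        return(sprintf("band %s has values outside [0, 1] where valid", b))
    }
    TRUE
  })

#' A complete synthetic scene
#'
#' Bundles the rendered [ReflectanceCube-class] with its generating truth:
#' per-pixel buffel presence, landscape strata, cover-class map, the rainfall
#' and fire realisations, the cover-class definitions and the config.
#'
#' @slot cube a [ReflectanceCube-class]
#' @slot truth integer grid matrix, 1 = buffel present
#' @slot strata integer grid matrix of landscape-stratum ids
#' @slot cover integer grid matrix indexing into `classes`
#' @slot classes list of [CoverClass-class] definitions
#' @slot rainfall the realised [RainfallSeries-class]
#' @slot fire the realised [FireSchedule-class]
#' @slot config the generating [SceneConfig-class]
#' @export
setClass("SyntheticScene",
  representation(cube = "ReflectanceCube", truth = "matrix", strata = "matrix",
                 cover = "matrix", classes = "list", rainfall = "RainfallSeries",
                 fire = "FireSchedule", config = "SceneConfig"),
  validity = function(object) {
    gr <- object@config@gridRows; gc <- object@config@gridCols
    for (nm in c("truth", "strata", "cover")) {
      m <- slot(object, nm)
      if (!identical(dim(m), c(gr, gc)))
        return(sprintf("'%s' grid does not conform to the configured dimensions", nm))
    }
    TRUE
  })

#' One vegetation index as a dates-by-pixels matrix
#'
#' The SVD substrate: rows are retained acquisition dates, columns are pixels
#' flattened row-major from the top-left. All residual missing values have
#' been imputed; `nImputed` records how many.
#'
#' @slot values numeric matrix (dates x pixels), no missing entries
#' @slot dates retained acquisition dates
#' @slot pixelIndex data.frame of pixel (row, col) per matrix column
#' @slot indexName which vegetation index (EVI, NBR, NDVI, NDWI)
#' @slot nImputed number of imputed entries
#' @slot geo geotransform list
#' @slot gridRows,gridCols grid dimensions
#' @export
setClass("SpatioTemporalMatrix",
  representation(values = "matrix", dates = "Date", pixelIndex = "data.frame",
                 indexName = "character", nImputed = "integer", geo = "list",
                 gridRows = "integer", gridCols = "integer"),
  validity = function(object) {
    if (nrow(object@values) != length(object@dates))
      return("row count must equal the number of retained dates")
    if (ncol(object@values) != nrow(object@pixelIndex))
      return("column count must equal the number of pixels")
    if (ncol(object@values) != object@gridRows * object@gridCols)
      return("column count must equal gridRows * gridCols")
    if (anyNA(object@values))
      return("matrix must contain no missing entries after imputation")
    TRUE
  })

#' Truncated SVD of a spatiotemporal matrix
#'
#' For a dates-by-pixels matrix M, stores the leading k singular values,
#' the temporal modes (left singular vectors, one value per date) and the
#' spatial loadings (right singular vectors, one value per pixel), plus each
#' component's share of the total squared variation sum(M^2).
#'
#' @slot singularValues nonincreasing nonnegative singular values
#' @slot temporalModes dates x k orthonormal matrix
#' @slot spatialLoadings pixels x k orthonormal matrix
#' @slot varianceFractions sigma_i^2 / sum(M^2)
#' @slot totalEnergy sum of squares of the full matrix
#' @slot indexName,dates,pixelIndex,geo,gridRows,gridCols provenance
#' @slot method "exact" or "randomized"
#' @export
setClass("DecompositionResult",
  representation(singularValues = "numeric", temporalModes = "matrix",
                 spatialLoadings = "matrix", varianceFractions = "numeric",
                 totalEnergy = "numeric", indexName = "character",
                 dates = "Date", pixelIndex = "data.frame", geo = "list",
                 gridRows = "integer", gridCols = "integer", method = "character"),
  validity = function(object) {
    s <- object@singularValues
    if (any(s < -1e-12)) return("singular values must be nonnegative")
    if (length(s) > 1 && any(diff(s) > 1e-8 * max(s, 1)))
      return("singular values must be sorted nonincreasing")
    if (sum(object@varianceFractions) > 1 + 1e-8)
      return("variance fractions must sum to at most 1")
    if (ncol(object@temporalModes) != length(s) ||
        ncol(object@spatialLoadings) != length(s))
      return("mode matrices must have one column per singular value")
    TRUE
  })

#' Per-pixel feature table of retained spatial loadings
#'
#' Rows are pixels (row-major grid order); columns are named
#' `<index>_<component>` (e.g. `ndvi_3`), the spatial-loading entries of the
#' retained SVD components of each vegetation index.
#'
#' @slot values pixels x features numeric matrix with column names
#' @slot pixelIndex data.frame of pixel (row, col)
#' @slot geo geotransform list
#' @slot gridRows,gridCols grid dimensions
#' @slot retainedK components kept per index
#' @slot indices the contributing index names
#' @export
setClass("FeatureTable",
  representation(values = "matrix", pixelIndex = "data.frame", geo = "list",
                 gridRows = "integer", gridCols = "integer",
                 retainedK = "integer", indices = "character"),
  validity = function(object) {
    if (is.null(colnames(object@values)))
      return("feature columns must be named")
    if (ncol(object@values) != object@retainedK * length(object@indices))
      return("column count must equal retainedK * number of indices")
    if (nrow(object@values) != nrow(object@pixelIndex))
      return("row count must match the pixel index")
    TRUE
  })

#' Fitted logistic occurrence model
#'
#' Intercept and coefficients over the features retained by forward-stepwise
#' BIC selection. `bicPath` records the BIC after each accepted step
#' (starting at the intercept-only model).
#'
#' @slot intercept numeric intercept beta_0
#' @slot coefficients named numeric coefficients over selected features
#' @slot selectedFeatures feature names in order of entry
#' @slot candidateFeatures all candidate feature names, canonical order
#' @slot bicPath BIC trajectory, intercept-only first
#' @slot metadata list (separation flag, dropped constants, ...)
#' @export
setClass("LogisticMapModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 selectedFeatures = "character", candidateFeatures = "character",
                 bicPath = "numeric", metadata = "list"),
  validity = function(object) {
    if (!all(object@selectedFeatures %in% object@candidateFeatures))
      return("selected features must be a subset of the candidates")
    if (!identical(names(object@coefficients), object@selectedFeatures))
      return("coefficients must be named by the selected features, in order")
    if (any(!is.finite(c(object@intercept, object@coefficients))))
      return("model parameters must be finite")
    TRUE
  })

#' Fitted tanh neural-network comparator
#'
#' A fixed 24 -> 3 (tanh) -> 1 (sigmoid) architecture trained by full-batch
#' quasi-Newton optimisation of the cross-entropy, with seeded initialisation.
#'
#' @slot W1,b1,W2,b2 layer weights and biases
#' @slot featureNames input feature names, training order
#' @slot spec architecture description list
#' @slot metadata training diagnostics (convergence, loss, restarts)
#' @export
setClass("NeuralNetModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "numeric", b2 = "numeric",
                 featureNames = "character", spec = "list", metadata = "list"),
  validity = function(object) {
    if (ncol(object@W1) != length(object@b1))
      return("hidden-layer weights and biases are inconsistent")
    if (nrow(object@W1) != length(object@featureNames))
      return("W1 must have one row per input feature")
    if (length(object@W2) != length(object@b1))
      return("output weights must match the hidden width")
    TRUE
  })

#' Per-pixel probability surface
#'
#' Grid of P(buffel) in \[0,1\] on the feature table's pixel grid.
#'
#' @slot prob numeric grid matrix of probabilities
#' @slot geo geotransform list
#' @slot modelId short identifier of the generating model
#' @export
setClass("ProbabilitySurface",
  representation(prob = "matrix", geo = "list", modelId = "character"),
  validity = function(object) {
    p <- object@prob
    if (anyNA(p) || any(p < 0 | p > 1))
      return("probabilities must lie in [0, 1] with no missing values")
    TRUE
  })

#' Bootstrap evaluation report
#'
#' Mean and standard error (SD over bootstraps / sqrt(n_boot)) of sensitivity,
#' specificity, accuracy and ROC-AUC, per split role, over repeated stratified
#' train/validation splits. All metrics are on the \[0,1\] scale.
#'
#' @slot metrics data.frame with columns role, metric, mean, se
#' @slot nBoot number of bootstrap splits
#' @slot trainFraction fraction of observations used for training
#' @slot metadata list (model label, resplit retries, seed)
#' @export
setClass("EvaluationReport",
  representation(metrics = "data.frame", nBoot = "integer",
                 trainFraction = "numeric", metadata = "list"),
  validity = function(object) {
    need <- c("role", "metric", "mean", "se")
    if (!all(need %in% names(object@metrics)))
      return("metrics must have columns role, metric, mean, se")
    ok <- is.na(object@metrics$mean) |
      (object@metrics$mean >= 0 & object@metrics$mean <= 1)
    if (!all(ok)) return("metric means must lie in [0, 1] (or be NA)")
    if (any(object@metrics$se < 0, na.rm = TRUE)) return("SE must be >= 0")
    TRUE
  })
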