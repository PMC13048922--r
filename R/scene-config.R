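#' Construct a scene configuration
#'
#' Defaults define the package's reference study conditions: a 64 x 64 pixel
#' landscape of six cover classes observed every 5 days over nine years
#' (2016-2024) with 68% of nominal acquisitions lost (leaving ~210 dates, of
#' which ~180 survive mosaic quality control), rainfall pulses at 4 events per
#' year with unit-mean exponential magnitudes, Beta(0.1, 20) per-date cloud
#' fractions, a 4% chance of a nodata swath gap per date, additive reflectance
#' noise with sd 0.02, and two fire events.
#'
#' @param gridRows,gridCols grid dimensions in pixels
#' @param startDate,endDate acquisition span (Date or "YYYY-MM-DD")
#' @param revisitDays nominal revisit interval in days
#' @param dropoutProb fraction of nominal acquisitions lost, in \[0, 1)
#' @param cloudBetaParams Beta shape parameters of the per-date cloud fraction
#' @param gapProb probability a date carries a nodata swath gap
#' @param noiseSd reflectance noise standard deviation
#' @param noiseType "additive" or "multiplicative"
#' @param rainRatePerYear rainfall-event rate (events / year)
#' @param rainMagnitudeMean mean exponential event magnitude
#' @param nFires number of fire events across the span
#' @param pixelSize ground pixel size in metres
#' @param seed integer master seed
#' @return a validated [SceneConfig-class]
#' @examples
#' cfg <- sceneConfig(gridRows = 8, gridCols = 8, seed = 1)
#' @export
sceneConfig <- function(gridRows = 64L, gridCols = 64L,
                        startDate = "2016-01-01", endDate = "2024-12-31",
                        revisitDays = 5, dropoutProb = 0.68,
                        cloudBetaParams = c(0.1, 20), gapProb = 0.04,
                        noiseSd = 0.02, noiseType = "additive",
                        rainRatePerYear = 4, rainMagnitudeMean = 1,
                        nFires = 2L, pixelSize = 10, seed = 42L) {
  new("SceneConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      startDate = as.Date(startDate), endDate = as.Date(endDate),
      revisitDays = as.numeric(revisitDays),
      dropoutProb = as.numeric(dropoutProb),
      cloudBetaParams = as.numeric(cloudBetaParams),
      gapProb = as.numeric(gapProb), noiseSd = as.numeric(noiseSd),
      noiseType = noiseType, rainRatePerYear = as.numeric(rainRatePerYear),
      rainMagnitudeMean = as.numeric(rainMagnitudeMean),
      nFires = as.integer(nFires), pixelSize = as.numeric(pixelSize),
      seed = as.integer(seed))
}

## Fixed simulator constants: plausible 5-band arid-zone endmembers
## (BLUE, GREEN, RED, NIR, SWIR1 surface reflectance). These are simulator
## defaults, not field measurements.
SOIL_ENDMEMBER <- c(BLUE = 0.12, GREEN = 0.18, RED = 0.26, NIR = 0.32,
                    SWIR1 = 0.42)
CHAR_ENDMEMBER <- c(BLUE = 0.05, GREEN = 0.06, RED = 0.07, NIR = 0.10,
                    SWIR1 = 0.30)
CLOUD_REFLECTANCE <- c(BLUE = 0.85, GREEN = 0.84, RED = 0.83, NIR = 0.80,
                       SWIR1 = 0.55)

#' Default cover-class definitions
#'
#' Six arid-zone cover classes with distinct rainfall-response phenologies.
#' The buffel class encodes the target's contrast with native grasses: a
#' strictly shorter lag, faster rise, higher amplitude and longer decay
#' half-life than either native tussock grass or spinifex, so after rain it
#' spikes sooner and higher and stays green longer.
#'
#' @return named list of [CoverClass-class] objects
#' @export
defaultCoverClasses <- function() {
  green <- function(blue, grn, red, nir, swir)
    c(BLUE = blue, GREEN = grn, RED = red, NIR = nir, SWIR1 = swir)
  list(
    buffel = CoverClass("buffel",
      PhenologyParams(lagDays = 3, riseRate = 0.20, decayHalflifeDays = 60,
                      amplitude = 0.90, baseline = 0.15),
      green(0.03, 0.06, 0.04, 0.45, 0.18)),
    native_tussock = CoverClass("native_tussock",
      PhenologyParams(lagDays = 6, riseRate = 0.10, decayHalflifeDays = 25,
                      amplitude = 0.50, baseline = 0.08),
      green(0.03, 0.06, 0.04, 0.45, 0.18)),
    spinifex = CoverClass("spinifex",
      PhenologyParams(lagDays = 8, riseRate = 0.07, decayHalflifeDays = 40,
                      amplitude = 0.30, baseline = 0.12),
      green(0.04, 0.07, 0.06, 0.35, 0.20)),
    shrub_canopy = CoverClass("shrub_canopy",
      PhenologyParams(lagDays = 10, riseRate = 0.05, decayHalflifeDays = 90,
                      amplitude = 0.25, baseline = 0.25),
      green(0.03, 0.06, 0.05, 0.40, 0.17)),
    bare = CoverClass("bare",
      PhenologyParams(lagDays = 10, riseRate = 0.05, decayHalflifeDays = 20,
                      amplitude = 0.05, baseline = 0.02),
      green(0.04, 0.07, 0.06, 0.38, 0.22)),
    riparian_woodland = CoverClass("riparian_woodland",
      PhenologyParams(lagDays = 5, riseRate = 0.08, decayHalflifeDays = 120,
                      amplitude = 0.35, baseline = 0.35),
      green(0.03, 0.06, 0.04, 0.43, 0.16))
  )
}
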