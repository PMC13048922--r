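# Shared fixtures: in-code cube construction, tiny scene configs, and the
# brute-force pairwise AUC oracle used to check the rank-based implementation.

# Build a ReflectanceCube directly from band matrices (pixels x dates).
# Bands given as a single value are broadcast.
makeCube <- function(gridRows, gridCols, dates,
                     bands = list(), quality = NULL, pixelSize = 10) {
  np <- gridRows * gridCols
  nd <- length(dates)
  full <- lapply(setNames(phenocube:::BAND_NAMES, phenocube:::BAND_NAMES),
                 function(b) {
    v <- bands[[b]]
    if (is.null(v)) v <- 0.25
    if (length(v) == 1L) matrix(v, np, nd) else v
  })
  if (is.null(quality)) quality <- matrix(0L, np, nd)
  pidx <- phenocube:::pixelIndexFrame(gridRows, gridCols)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = c(full, list(quality = quality)),
    rowData = S4Vectors::DataFrame(pixel_row = pidx$row, pixel_col = pidx$col),
    colData = S4Vectors::DataFrame(date = as.Date(dates)))
  S4Vectors::metadata(se) <- list(gridRows = gridRows, gridCols = gridCols,
                                  geo = phenocube:::defaultGeo(gridRows, pixelSize))
  new("ReflectanceCube", se)
}

# Small, fast scene for pipeline-level tests; `...` overrides any default.
tinySceneConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(gridRows = 16L, gridCols = 16L, startDate = "2020-01-01",
         endDate = "2021-12-31", dropoutProb = 0.3, nFires = 1L, seed = seed),
    list(...))
  do.call(sceneConfig, args)
}

# O(n^2) pairwise concordance oracle: probability a random positive
# outranks a random negative, half credit for ties.
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

emptyRain <- function(origin = "2020-01-01") {
  new("RainfallSeries", origin = as.Date(origin), times = numeric(0),
      magnitudes = numeric(0))
}

noFire <- function(origin = "2020-01-01") {
  new("FireSchedule", origin = as.Date(origin), events = list())
}
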