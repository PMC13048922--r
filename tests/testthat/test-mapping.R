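# Probability surfaces, occurrence maps and stratum summaries.

makeFeatureTable <- function(values, gridRows, gridCols) {
  new("FeatureTable", values = values,
      pixelIndex = phenocube:::pixelIndexFrame(gridRows, gridCols),
      geo = phenocube:::defaultGeo(gridRows), gridRows = gridRows,
      gridCols = gridCols, retainedK = ncol(values),
      indices = "ndvi")
}

makeModel <- function(intercept, coefficients = setNames(numeric(0), character(0)),
                      candidates = names(coefficients)) {
  if (is.null(candidates)) candidates <- character(0)
  new("LogisticMapModel", intercept = intercept, coefficients = coefficients,
      selectedFeatures = names(coefficients),
      candidateFeatures = union(candidates, names(coefficients)),
      bicPath = 0, metadata = list())
}

test_that("the surface applies the standard rising logistic transform", {
  ft <- makeFeatureTable(matrix(0, 4, 1, dimnames = list(NULL, "ndvi_1")),
                         2L, 2L)
  # intercept -2.92, all features zero: P = 1/(1 + exp(2.92)) = 0.0512
  s <- predictSurface(makeModel(-2.92), ft)
  expect_equal(unique(as.vector(probabilityGrid(s))), 0.0512, tolerance = 1e-3)
  # Lin = 0 is the logistic midpoint
  expect_equal(as.vector(probabilityGrid(predictSurface(makeModel(0), ft))),
               rep(0.5, 4))
  # the printed convention inverts probabilities (and says so)
  expect_message(sPr <- predictSurface(makeModel(-2.92), ft,
                                       logitSign = "printed"), "inverted")
  expect_equal(probabilityGrid(sPr), 1 - probabilityGrid(s))

  # monotone in a positive-coefficient feature
  ft2 <- makeFeatureTable(matrix(seq(-1, 1, length.out = 4), 4, 1,
                                 dimnames = list(NULL, "ndvi_1")), 2L, 2L)
  m2 <- makeModel(0, c(ndvi_1 = 2))
  p2 <- probabilityGrid(predictSurface(m2, ft2))
  expect_true(all(diff(phenocube:::flattenGrid(p2)) > 0))
  # a missing feature column is named in the error
  expect_error(predictSurface(makeModel(0, c(evi_9 = 1)), ft2), "evi_9")
})

test_that("surface values map pixels back to their grid positions", {
  vals <- matrix(seq(-3, 3, length.out = 6), 6, 1,
                 dimnames = list(NULL, "ndvi_1"))
  ft <- makeFeatureTable(vals, 2L, 3L)
  s <- predictSurface(makeModel(0, c(ndvi_1 = 1)), ft)
  # row-major: pixel 5 is grid (2, 2)
  expect_equal(probabilityGrid(s)[2, 2], plogis(vals[5, 1]),
               ignore_attr = TRUE)
})

test_that("thresholding uses the inclusive boundary and is monotone", {
  ft <- makeFeatureTable(matrix(qlogis(c(0.49, 0.50, 0.51, 0.2)), 4, 1,
                                dimnames = list(NULL, "ndvi_1")), 2L, 2L)
  s <- predictSurface(makeModel(0, c(ndvi_1 = 1)), ft)
  occ <- thresholdMap(s, 0.5)
  expect_equal(phenocube:::flattenGrid(occ), c(0L, 1L, 1L, 0L))
  expect_equal(attr(occ, "occupied"), 2L)
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(t) attr(thresholdMap(s, t), "occupied"), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(thresholdMap(s, 1), "outside")
})

test_that("stratum summaries count threshold exceedances per stratum", {
  P <- matrix(c(0.6, 0.6, 0.8, 0.2), 2, 2)
  s <- new("ProbabilitySurface", prob = P, geo = phenocube:::defaultGeo(2),
           modelId = "test")
  one <- strataSummary(s, matrix(1L, 2, 2))
  expect_equal(one$p50, 0.75)
  expect_equal(one$p75, 0.25)
  expect_equal(one$area_km2, 4 * 1e-4)        # four 10 m pixels

  sAll1 <- new("ProbabilitySurface", prob = matrix(1, 2, 2),
               geo = phenocube:::defaultGeo(2), modelId = "test")
  all1 <- strataSummary(sAll1, matrix(1L, 2, 2))
  expect_equal(all1$p50, 1)
  expect_equal(all1$p75, 1)

  # nested thresholds and area conservation across strata
  sc <- simulateScene(tinySceneConfig(seed = 41))
  Pr <- matrix(phenocube:::withSeed(4, runif(256)), 16, 16)
  surf <- new("ProbabilitySurface", prob = Pr,
              geo = phenocube:::defaultGeo(16), modelId = "test")
  tab <- strataSummary(surf, strataMap(sc))
  expect_true(all(tab$p75 <= tab$p50))
  expect_equal(sum(tab$n_pixels), 256L)
})

test_that("stratum accuracies partition the whole-map confusion", {
  sc <- simulateScene(tinySceneConfig(seed = 43))
  truth <- truthLabels(sc)
  wp <- sampleWaypoints(sc, 120, seed = 6)
  geo <- phenocube:::defaultGeo(16)

  perfect <- new("ProbabilitySurface", prob = truth * 0.98 + 0.01,
                 geo = geo, modelId = "perfect")
  accP <- strataAccuracy(perfect, wp, 0.5)
  expect_true(all(accP$accuracy == 1))

  anti <- new("ProbabilitySurface", prob = (1 - truth) * 0.98 + 0.01,
              geo = geo, modelId = "anti")
  accA <- strataAccuracy(anti, wp, 0.5)
  expect_true(all(accA$accuracy == 0))

  # pooled row equals the confusion computed over all waypoints at once
  noisy <- new("ProbabilitySurface",
               prob = phenocube:::clip01(truth * 0.8 + 0.1 +
                 matrix(phenocube:::withSeed(2, rnorm(256, 0, 0.25)), 16, 16)),
               geo = geo, modelId = "noisy")
  acc <- strataAccuracy(noisy, wp, 0.5)
  P <- probabilityGrid(noisy)
  pred <- as.integer(P[cbind(wp$pixel_row, wp$pixel_col)] >= 0.5)
  whole <- confusionMetrics(pred, as.integer(wp$label == "buffel"))
  pooled <- acc[acc$stratum == "all", ]
  expect_equal(pooled$accuracy, whole[["accuracy"]])
  expect_equal(pooled$sensitivity, whole[["sensitivity"]])
  expect_equal(pooled$specificity, whole[["specificity"]])
  # waypoint counts partition
  expect_equal(sum(acc$n_waypoints[acc$stratum != "all"]), 120L)
})
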