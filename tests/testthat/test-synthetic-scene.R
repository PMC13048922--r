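# The synthetic-scene generator: acquisition calendar, rainfall process,
# phenology kernel, rendering, and waypoint sampling.

test_that("acquisition dates follow the revisit interval and seeded dropout", {
  cfg <- sceneConfig(gridRows = 4, gridCols = 4, startDate = "2020-01-01",
                     endDate = "2020-04-10", revisitDays = 5,
                     dropoutProb = 0, seed = 1)
  d <- generateDates(cfg)
  expect_length(d, 21L)                       # 100-day span, inclusive endpoints
  expect_true(all(diff(as.numeric(d)) == 5))

  # dropout = 1 violates the config invariant
  expect_error(sceneConfig(dropoutProb = 1), "dropoutProb")

  # seeded dropout is deterministic and thins roughly by the dropout rate
  cfg2 <- sceneConfig(gridRows = 4, gridCols = 4, startDate = "2015-12-01",
                      endDate = "2025-02-28", revisitDays = 5,
                      dropoutProb = 0.5, seed = 7)
  d1 <- generateDates(cfg2)
  d2 <- generateDates(cfg2)
  expect_identical(d1, d2)
  expect_true(all(diff(as.numeric(d1)) > 0))
  nominal <- length(seq(cfg2@startDate, cfg2@endDate, by = 5))
  expect_gt(length(d1), 0.5 * nominal - 4 * sqrt(nominal * 0.25))
  expect_lt(length(d1), 0.5 * nominal + 4 * sqrt(nominal * 0.25))

  # span shorter than the revisit interval is degenerate
  expect_error(generateDates(sceneConfig(startDate = "2020-01-01",
                                         endDate = "2020-01-03",
                                         revisitDays = 5)), "degenerate")
})

test_that("rainfall is a seeded Poisson process with exponential magnitudes", {
  span <- as.Date("2015-12-01") + c(0, 3360)   # 9.2 years
  r1 <- simulateRainfall(span, ratePerYear = 4, seed = 3)
  r2 <- simulateRainfall(span, ratePerYear = 4, seed = 3)
  expect_identical(r1@times, r2@times)
  expect_identical(r1@magnitudes, r2@magnitudes)
  expect_true(all(diff(r1@times) > 0))
  expect_true(all(eventMagnitudes(r1) >= 0))
  expect_error(simulateRainfall(span, ratePerYear = 0), "ratePerYear")

  # vanishing intensity: almost surely no events
  expect_length(simulateRainfall(as.Date("2020-01-01") + c(0, 365),
                                 ratePerYear = 1e-4, seed = 1)@times, 0L)

  # Monte-Carlo mean event count: Poisson mean = rate x span / 365.25 = 36.8
  counts <- vapply(1:10000, function(s)
    length(simulateRainfall(span, ratePerYear = 4, seed = s)@times),
    numeric(1))
  expect_lt(abs(mean(counts) - 36.8), 3 * sqrt(36.8 / 10000))
})

test_that("greenness traces encode the buffel/native phenological contrast", {
  dates <- as.Date("2020-01-01") + 0:200
  classes <- defaultCoverClasses()
  buffel <- classes$buffel@phenology
  native <- classes$native_tussock@phenology

  # no rain, no fire: flat baseline
  expect_equal(greennessTrace(buffel, emptyRain(), dates),
               rep(buffel@baseline, length(dates)))

  # single unit pulse at day 10: buffel peaks higher and stays higher at
  # every date after the pulse
  rain <- new("RainfallSeries", origin = as.Date("2020-01-01"),
              times = 10, magnitudes = 1)
  gB <- greennessTrace(buffel, rain, dates)
  gN <- greennessTrace(native, rain, dates)
  expect_gt(max(gB), max(gN))
  post <- as.numeric(dates - rain@origin) > 10
  expect_true(all(gB[post] > gN[post]))

  # severity-1 fire extinguishes greenness at the fire date
  gF <- greennessTrace(buffel, rain, dates, fireTimes = 50, fireSeverities = 1)
  expect_equal(gF[as.numeric(dates - rain@origin) == 50], 0)
  expect_true(all(gF <= gB + 1e-12))
})

test_that("rendered reflectance hits the mixture limits and stays in [0,1]", {
  dates <- as.Date("2020-01-01") + c(0, 10, 20)
  cfg <- sceneConfig(gridRows = 2, gridCols = 2, startDate = "2020-01-01",
                     endDate = "2020-02-01", noiseSd = 0, gapProb = 0,
                     cloudBetaParams = c(1e-4, 1e4), seed = 5)
  mkClass <- function(baseline) CoverClass("bare",
    PhenologyParams(0, 0, 10, 0, baseline),
    c(BLUE = 0.03, GREEN = 0.06, RED = 0.04, NIR = 0.45, SWIR1 = 0.18))
  cover <- matrix(1L, 2, 2)

  # g = 0 everywhere: soil endmember exactly (at valid pixels)
  cube0 <- renderReflectance(cover, list(mkClass(0)), emptyRain(), noFire(),
                             dates, cfg)
  ok <- validMask(cube0)
  for (b in phenocube:::BAND_NAMES)
    expect_equal(unique(bandMatrix(cube0, b)[ok]),
                 unname(phenocube:::SOIL_ENDMEMBER[[b]]))

  # g = 1: the vegetation endmember exactly
  cube1 <- renderReflectance(cover, list(mkClass(1)), emptyRain(), noFire(),
                             dates, cfg)
  ok <- validMask(cube1)
  expect_equal(unique(bandMatrix(cube1, "NIR")[ok]), 0.45)
  expect_equal(unique(bandMatrix(cube1, "SWIR1")[ok]), 0.18)

  # conservation: all rendered reflectance in [0,1]; nodata flagged not zeroed
  sc <- simulateScene(tinySceneConfig(seed = 2, gapProb = 0.5))
  cube <- reflectanceCube(sc)
  for (b in phenocube:::BAND_NAMES) {
    v <- bandMatrix(cube, b)
    expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
    expect_true(all(is.na(v[qualityMatrix(cube) == 2L])))
  }
})

test_that("fire strictly depresses NBR for burned pixels only", {
  cfg <- sceneConfig(gridRows = 4, gridCols = 4, startDate = "2020-01-01",
                     endDate = "2020-12-31", noiseSd = 0, gapProb = 0,
                     cloudBetaParams = c(1e-4, 1e4), dropoutProb = 0,
                     seed = 8)
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  fire <- new("FireSchedule", origin = as.Date("2020-01-01"),
              events = list(list(time = 100, mask = mask, severity = 0.8)))
  sc <- simulateScene(cfg, fires = fire)
  nbr <- computeIndex(reflectanceCube(sc), "NBR")
  dates <- acquisitionDates(reflectanceCube(sc))
  t <- as.numeric(dates - as.Date("2020-01-01"))
  pre <- max(which(t < 100)); post <- min(which(t >= 100))
  burnedVec <- phenocube:::flattenGrid(mask)
  expect_true(all(nbr[burnedVec, post] < nbr[burnedVec, pre]))
  # unburned pixels: NBR moves only with phenology, not with the fire;
  # compare against a fire-free rendering of the same scene
  sc0 <- simulateScene(cfg, fires = noFire("2020-01-01"))
  nbr0 <- computeIndex(reflectanceCube(sc0), "NBR")
  expect_equal(nbr[!burnedVec, ], nbr0[!burnedVec, ])
})

test_that("buffel mean NDVI majorizes native tussock after every rain event", {
  cfg <- tinySceneConfig(seed = 11, noiseSd = 0, nFires = 0L, gapProb = 0,
                         cloudBetaParams = c(1e-4, 1e4))
  sc <- simulateScene(cfg)
  cube <- reflectanceCube(sc)
  ndvi <- computeIndex(cube, "NDVI")
  cover <- phenocube:::flattenGrid(coverMap(sc))
  isB <- cover == match("buffel", names(defaultCoverClasses()))
  isN <- cover == match("native_tussock", names(defaultCoverClasses()))
  expect_gt(sum(isB), 0); expect_gt(sum(isN), 0)
  mB <- colMeans(ndvi[isB, , drop = FALSE], na.rm = TRUE)
  mN <- colMeans(ndvi[isN, , drop = FALSE], na.rm = TRUE)
  t <- as.numeric(acquisitionDates(cube) - rainfallSeries(sc)@origin)
  for (te in rainfallSeries(sc)@times) {
    win <- t > te & t <= te + 60
    expect_true(all(mB[win] >= mN[win]))
  }
})

test_that("identical config and seed reproduce a bit-identical scene", {
  cfg <- tinySceneConfig(seed = 21)
  s1 <- simulateScene(cfg)
  s2 <- simulateScene(cfg)
  expect_identical(truthLabels(s1), truthLabels(s2))
  expect_identical(strataMap(s1), strataMap(s2))
  for (b in phenocube:::BAND_NAMES)
    expect_identical(bandMatrix(reflectanceCube(s1), b),
                     bandMatrix(reflectanceCube(s2), b))
  expect_identical(sampleWaypoints(s1, 50, seed = 4),
                   sampleWaypoints(s2, 50, seed = 4))
})

test_that("waypoint sampling respects truth, strata and determinism", {
  sc <- simulateScene(tinySceneConfig(seed = 31))
  np <- prod(gridDims(sc))

  # exhaustive sample: labels match truth exactly
  wp <- sampleWaypoints(sc, np, stratified = FALSE, seed = 1)
  expect_equal(nrow(wp), np)
  expect_equal(wp$label == "buffel",
               phenocube:::flattenGrid(truthLabels(sc)) == 1L)

  # per-stratum counts honoured
  ids <- sort(unique(as.vector(strataMap(sc))))
  wp2 <- sampleWaypoints(sc, rep(10L, length(ids)), stratified = TRUE, seed = 2)
  expect_equal(unname(table(wp2$stratum))[seq_along(ids)], rep(10L, length(ids)),
               ignore_attr = TRUE)

  # overdrawing a stratum errors, naming it
  sizes <- tabulate(match(as.vector(strataMap(sc)), ids))
  small <- ids[which.min(sizes)]
  ask <- setNames(rep(1L, length(ids)), ids)
  ask[as.character(small)] <- min(sizes) + 1L   # overdraw just that stratum
  expect_error(sampleWaypoints(sc, ask, stratified = TRUE, seed = 3),
               paste("stratum", small))
})
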