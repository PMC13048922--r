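# Truncated SVD, sign normalisation, and feature assembly.

test_that("decomposition recovers rank and variance partition in closed form", {
  # rank-1 outer product: one nonzero singular value takes all the variance
  u <- 1:5; v <- seq(0.1, 1, length.out = 8)
  M <- outer(u, v)
  d1 <- decomposeMatrix(M, k = 3)
  expect_equal(varianceFractions(d1), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(singularValues(d1)[1], sqrt(sum(u^2) * sum(v^2)))

  # diag(6..1): singular values 6..1; top-2 fraction (36+25)/91
  d2 <- decomposeMatrix(diag(6:1), k = 6)
  expect_equal(singularValues(d2), as.numeric(6:1))
  expect_equal(sum(varianceFractions(d2)[1:2]), 61 / 91)

  # k beyond the rank bound errors
  expect_error(decomposeMatrix(M, k = 6), "rank bound")
})

test_that("randomized decomposition matches the exact oracle", {
  M <- phenocube:::withSeed(101, matrix(rnorm(50 * 400), 50, 400))
  ex <- decomposeMatrix(M, 6, method = "exact")
  rz <- decomposeMatrix(M, 6, method = "randomized", seed = 3)
  expect_lt(max(abs(singularValues(rz) - singularValues(ex)) /
                  singularValues(ex)), 1e-6)
  ang <- acos(pmin(1, svd(crossprod(temporalModes(ex), temporalModes(rz)))$d))
  expect_lt(max(ang), 1e-4)
})

test_that("sign normalisation is canonical, idempotent and lossless", {
  M <- phenocube:::withSeed(5, matrix(rnorm(20 * 30), 20, 30))
  d <- decomposeMatrix(M, 4)
  # idempotent
  expect_identical(signNormalize(d), d)
  # flipping a pair is undone
  flipped <- d
  flipped@temporalModes[, 2] <- -flipped@temporalModes[, 2]
  flipped@spatialLoadings[, 2] <- -flipped@spatialLoadings[, 2]
  restored <- signNormalize(flipped)
  expect_equal(restored@temporalModes, d@temporalModes)
  expect_equal(restored@spatialLoadings, d@spatialLoadings)
  # reconstruction is unchanged by normalisation
  recon <- function(x) temporalModes(x) %*% diag(singularValues(x)) %*%
    t(spatialLoadings(x))
  expect_equal(recon(flipped), recon(d))
  # canonical convention: each temporal mode's max-|.| entry is positive
  for (i in 1:4) {
    m <- which.max(abs(temporalModes(d)[, i]))
    expect_gt(temporalModes(d)[m, i], 0)
  }
})

test_that("truncation obeys Eckart-Young and cumulative variance monotonicity", {
  M <- phenocube:::withSeed(9, matrix(rnorm(15 * 40), 15, 40))
  full <- svd(M)
  err <- cum <- numeric(10)
  for (k in 1:10) {
    d <- decomposeMatrix(M, k)
    recon <- temporalModes(d) %*% diag(singularValues(d), k) %*%
      t(spatialLoadings(d))
    err[k] <- sum((M - recon)^2)
    cum[k] <- sum(varianceFractions(d))
    expect_equal(err[k], sum(full$d[-seq_len(k)]^2), tolerance = 1e-8)
  }
  expect_true(all(diff(err) <= 1e-8))
  expect_true(all(diff(cum) >= -1e-12))
})

test_that("feature assembly yields named 24-column tables from 4 indices", {
  sc <- simulateScene(tinySceneConfig(seed = 13))
  mats <- buildIndexMatrices(reflectanceCube(sc))
  dec <- lapply(mats, decomposeMatrix, k = 6)
  ft <- extractFeatures(dec, retainedK = 6)
  expect_equal(ncol(featureMatrix(ft)), 24L)
  expect_true(all(c("ndvi_1", "ndvi_6", "evi_5", "nbr_2", "ndwi_3") %in%
                    colnames(featureMatrix(ft))))
  # the named column is that index's component loading, entry for entry
  expect_equal(featureMatrix(ft)[, "evi_5"],
               unname(spatialLoadings(dec$evi)[, 5]))
  # single index, k = 1: exactly the leading spatial loading
  ft1 <- extractFeatures(dec["ndvi"], retainedK = 1)
  expect_equal(unname(featureMatrix(ft1)[, 1]),
               unname(spatialLoadings(dec$ndvi)[, 1]))
  # index processing order only renames/permutes columns
  ftR <- extractFeatures(rev(dec), retainedK = 6)
  expect_equal(featureMatrix(ftR)[, colnames(featureMatrix(ft))],
               featureMatrix(ft))
  # mismatched pixel grids are refused
  short <- decomposeMatrix(matrixValues(mats$ndvi)[, 1:10], k = 2)
  expect_error(extractFeatures(list(a = short, b = dec$evi), retainedK = 2),
               "mismatched")
})

test_that("a noise-free scene spanned by few temporal patterns is low-rank", {
  cfg <- tinySceneConfig(seed = 17, noiseSd = 0, nFires = 0L, gapProb = 0,
                         cloudBetaParams = c(1e-4, 1e4))
  sc <- simulateScene(cfg)
  mats <- buildIndexMatrices(reflectanceCube(sc))
  for (m in mats) {
    d <- decomposeMatrix(m, k = 6)
    expect_gte(sum(varianceFractions(d)), 0.99)
  }
})

test_that("waypoint feature lookup uses nearest centers with documented ties", {
  sc <- simulateScene(tinySceneConfig(seed = 19))
  mats <- buildIndexMatrices(reflectanceCube(sc))
  ft <- extractFeatures(lapply(mats, decomposeMatrix, k = 6))
  geo <- geoMeta(ft)

  # a waypoint at a pixel center returns that pixel's row
  wp <- data.frame(x = geo$originX + 2.5 * geo$pixelSize,
                   y = geo$originY - 3.5 * geo$pixelSize, label = "buffel")
  out <- featuresAtWaypoints(ft, wp)
  expect_equal(out$pixel_row, 4L)
  expect_equal(out$pixel_col, 3L)
  j <- (4L - 1L) * 16L + 3L
  expect_equal(unlist(out[1, colnames(featureMatrix(ft))]),
               featureMatrix(ft)[j, ])

  # shared corner of 4 pixels: smallest row, then column
  wpC <- data.frame(x = geo$originX + 3 * geo$pixelSize,
                    y = geo$originY - 3 * geo$pixelSize, label = "buffel")
  outC <- featuresAtWaypoints(ft, wpC)
  expect_equal(c(outC$pixel_row, outC$pixel_col), c(3L, 3L))

  # duplicates in one pixel: warn, keep the first
  wpD <- data.frame(x = rep(geo$originX + 1.5 * geo$pixelSize, 2),
                    y = rep(geo$originY - 1.5 * geo$pixelSize, 2),
                    label = c("buffel", "buffel_free"))
  expect_warning(outD <- featuresAtWaypoints(ft, wpD), "keeping the first")
  expect_equal(nrow(outD), 1L)
  expect_equal(outD$label, 1L)

  # outside the extent: error carries the coordinates
  expect_error(featuresAtWaypoints(ft, data.frame(x = -999, y = 5,
                                                  label = "buffel")),
               "-999")
})
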