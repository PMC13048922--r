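## Synthetic arid-phenology scene generator.
##
## The generator emulates the statistical structure the downstream analysis
## relies on: irregularly revisited acquisitions, rainfall-pulse greenness in
## which buffel grass responds faster, higher and longer than native grasses,
## fire events that depress the burn ratio, cloud/nodata dropout, and a
## blocky cover-class mosaic with a riparian corridor. All randomness flows
## through seeds derived from the SceneConfig master seed.

#' Generate acquisition dates
#'
#' Nominal dates at the configured revisit interval (inclusive of the start,
#' and of the end when the span is a multiple of the interval), thinned by
#' seeded independent dropout.
#'
#' @param config a [SceneConfig-class]
#' @return strictly increasing Date vector
#' @examples
#' cfg <- sceneConfig(startDate = "2020-01-01", endDate = "2020-04-10",
#'                    dropoutProb = 0, seed = 1)
#' length(generateDates(cfg))  # 21 dates over a 100-day span at revisit 5
#' @export
generateDates <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  nominal <- seq(config@startDate, config@endDate, by = config@revisitDays)
  if (length(nominal) < 2L)
    stop("degenerate config: span shorter than the revisit interval", call. = FALSE)
  keep <- withSeed(childSeed(config@seed, 1L),
                   runif(length(nominal)) >= config@dropoutProb)
  dates <- nominal[keep]
  if (length(dates) < 2L)
    stop("degenerate config: dropout left fewer than two acquisition dates",
         call. = FALSE)
  dates
}

#' Simulate a rainfall-pulse series
#'
#' A homogeneous Poisson process of rain events over the span of `dates`,
#' with independent exponential magnitudes. Event times are continuous day
#' offsets from the first date.
#'
#' @param dates Date vector defining the span
#' @param ratePerYear expected events per 365.25-day year (> 0)
#' @param magnitudeMean mean of the exponential magnitudes
#' @param seed integer seed
#' @return a [RainfallSeries-class]
#' @export
simulateRainfall <- function(dates, ratePerYear, magnitudeMean = 1, seed = 1L) {
  stopifnot_scalar(ratePerYear, "ratePerYear", min = 0, strict_min = TRUE)
  stopifnot_scalar(magnitudeMean, "magnitudeMean", min = 0, strict_min = TRUE)
  dates <- as.Date(dates)
  spanDays <- as.numeric(max(dates) - min(dates))
  withSeed(seed, {
    n <- rpois(1L, ratePerYear * spanDays / 365.25)
    times <- sort(runif(n, 0, spanDays))
    mags <- rexp(n, rate = 1 / magnitudeMean)
  })
  ## coincident times (probability zero up to floating point) would violate
  ## the strict-increase invariant; nudge deterministically
  while (length(times) > 1 && any(diff(times) <= 0))
    times[c(FALSE, diff(times) <= 0)] <- times[c(FALSE, diff(times) <= 0)] + 1e-6
  new("RainfallSeries", origin = min(dates), times = times, magnitudes = mags)
}

# Rise-then-decay response kernel. u is days since the (post-lag) response
# onset: linear rise at `riseRate` per day up to 1 at u = 1/riseRate, then
# exponential decay with the stated half-life. Zero for u < 0.
greennessKernel <- function(u, riseRate, decayHalflifeDays) {
  k <- numeric(length(u))
  if (riseRate <= 0) return(k)
  tPeak <- 1 / riseRate
  rising <- u >= 0 & u <= tPeak
  fading <- u > tPeak
  k[rising] <- u[rising] * riseRate
  if (decayHalflifeDays <= 0) {
    k[fading] <- 0
  } else {
    k[fading] <- exp(-log(2) * (u[fading] - tPeak) / decayHalflifeDays)
  }
  k
}

# Multiplicative fire suppression of greenness for one pixel's event history:
# drops to (1 - severity) at the fire date and recovers along the class's own
# decay kernel (the burn effect fades with the phenology half-life).
fireSuppression <- function(tDays, fireTimes, fireSeverities, decayHalflifeDays) {
  f <- rep(1, length(tDays))
  for (i in seq_along(fireTimes)) {
    u <- tDays - fireTimes[i]
    hit <- u >= 0
    fade <- if (decayHalflifeDays > 0)
      exp(-log(2) * u[hit] / decayHalflifeDays) else as.numeric(u[hit] == 0)
    f[hit] <- f[hit] * (1 - fireSeverities[i] * fade)
  }
  f
}

#' Greenness trace of one pixel
#'
#' Fractional green cover over `dates` for a cover class with phenology
#' `params`: baseline plus, for each rain event, amplitude x magnitude x a
#' rise-then-exponential-decay kernel delayed by the class lag; clipped to
#' \[0,1\]. Fire events experienced by the pixel multiply the trace by
#' (1 - severity) at the fire date, the suppression fading with the class's
#' decay half-life.
#'
#' @param params a [PhenologyParams-class]
#' @param rain a [RainfallSeries-class]
#' @param dates nonempty Date vector
#' @param fireTimes,fireSeverities the pixel's fire history as day offsets
#'   from the rain origin and severities in \[0,1\]
#' @return numeric vector of green fractions, one per date
#' @export
greennessTrace <- function(params, rain, dates, fireTimes = numeric(0),
                           fireSeverities = numeric(0)) {
  stopifnot(is(params, "PhenologyParams"), is(rain, "RainfallSeries"))
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("dates must be nonempty", call. = FALSE)
  t <- as.numeric(dates - rain@origin)
  g <- rep(params@baseline, length(t))
  for (i in seq_along(rain@times)) {
    u <- t - rain@times[i] - params@lagDays
    g <- g + params@amplitude * rain@magnitudes[i] *
      greennessKernel(u, params@riseRate, params@decayHalflifeDays)
  }
  g <- clip01(g)
  if (length(fireTimes))
    g <- g * fireSuppression(t, fireTimes, fireSeverities,
                             params@decayHalflifeDays)
  clip01(g)
}

## --- landscape layout ------------------------------------------------------

# Strata: 1 = alluvial floodplain (riparian corridor), 2 = sandplain,
# 3 = rocky hills. Cover classes tile in blocks within each stratum so the
# mosaic has contiguous stands, with stratum-specific class frequencies
# (floodplain heavily infested, hills nearly buffel-free).
makeLandscape <- function(gridRows, gridCols, seed) {
  strata <- matrix(2L, gridRows, gridCols)
  rows <- matrix(seq_len(gridRows), gridRows, gridCols)
  cols <- matrix(seq_len(gridCols), gridRows, gridCols, byrow = TRUE)
  ## sinuous riparian corridor running down the grid
  center <- gridCols * (0.30 + 0.35 * seq_len(gridRows) / gridRows) +
    0.08 * gridCols * sin(2 * pi * seq_len(gridRows) / gridRows * 1.5)
  halfWidth <- max(1.5, 0.05 * gridCols)
  corridor <- abs(cols - center[rows]) <= halfWidth
  ## rocky hills block in the top-right
  hills <- rows <= ceiling(0.30 * gridRows) & cols >= ceiling(0.60 * gridCols)
  strata[hills] <- 3L
  strata[corridor] <- 1L

  classNames <- names(defaultCoverClasses())
  freq <- list(
    `1` = c(buffel = 0.50, riparian_woodland = 0.38, native_tussock = 0.12),
    `2` = c(buffel = 0.22, native_tussock = 0.30, spinifex = 0.25,
            shrub_canopy = 0.18, bare = 0.05),
    `3` = c(buffel = 0.08, spinifex = 0.45, bare = 0.35, shrub_canopy = 0.12))
  bs <- max(4L, as.integer(round(gridRows / 8)))
  blockOf <- (rows - 1L) %/% bs * ((gridCols - 1L) %/% bs + 1L) +
    (cols - 1L) %/% bs
  cover <- matrix(NA_integer_, gridRows, gridCols)
  withSeed(seed, {
    for (b in sort(unique(as.vector(blockOf)))) {
      inBlock <- blockOf == b
      for (s in unique(strata[inBlock])) {
        p <- freq[[as.character(s)]]
        cls <- sample(names(p), 1L, prob = p)
        cover[inBlock & strata == s] <- match(cls, classNames)
      }
    }
  })
  list(strata = strata, cover = cover,
       strataNames = c("alluvial_floodplain", "sandplain", "rocky_hills"))
}

# A seeded contiguous rectangle covering ~`fraction` of the grid (row-major
# logical vector). Clouds and swath gaps use this.
randomRectangle <- function(gridRows, gridCols, fraction) {
  area <- max(1, round(fraction * gridRows * gridCols))
  aspect <- exp(runif(1, -0.7, 0.7))
  h <- max(1L, min(gridRows, as.integer(round(sqrt(area * aspect)))))
  w <- max(1L, min(gridCols, as.integer(ceiling(area / h))))
  r0 <- sample.int(gridRows - h + 1L, 1L)
  c0 <- sample.int(gridCols - w + 1L, 1L)
  m <- matrix(FALSE, gridRows, gridCols)
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
  m
}

# row-major flattening of a grid matrix (pixel 1 = top-left, then across)
flattenGrid <- function(m) as.vector(t(m))

#' Render a reflectance cube from scene state
#'
#' Linear spectral mixture per pixel and date: green fraction times the
#' class's vegetation endmember plus (1 - green) times the soil endmember;
#' burned pixels blend towards a char endmember (SWIR1-raised, NIR-depressed)
#' with exponentially fading intensity so NBR drops at fire dates; then
#' Gaussian noise, clipped to \[0,1\]. Per-date cloud fractions are drawn
#' from the configured Beta distribution and applied as one contiguous
#' rectangle (quality code 1); swath gaps appear with probability `gapProb`
#' as nodata rectangles (quality code 2).
#'
#' @param cover integer grid matrix of class indices into `classes`
#' @param classes list of [CoverClass-class] definitions
#' @param rain a [RainfallSeries-class]
#' @param fire a [FireSchedule-class]
#' @param dates acquisition Date vector
#' @param config the [SceneConfig-class] (noise, cloud and geometry settings)
#' @return a [ReflectanceCube-class]
#' @export
renderReflectance <- function(cover, classes, rain, fire, dates, config) {
  gr <- config@gridRows; gc <- config@gridCols
  np <- gr * gc; nd <- length(dates)
  classVec <- flattenGrid(cover)
  t <- as.numeric(as.Date(dates) - rain@origin)

  ## per-class greenness base traces (no fire)
  gClass <- t(vapply(classes, function(cl)
    greennessTrace(cl@phenology, rain, dates), numeric(nd)))
  G <- gClass[classVec, , drop = FALSE]              # pixels x dates
  dimnames(G) <- NULL

  ## fire: greenness suppression (class-specific recovery) + char blending
  B <- matrix(0, np, nd)                             # char blend intensity
  charFadeHalflife <- 180                            # fire-scar persistence, days
  for (ev in fire@events) {
    burned <- flattenGrid(ev$mask)
    if (!any(burned)) next
    u <- t - ev$time
    charFade <- ifelse(u >= 0, ev$severity * exp(-log(2) * pmax(u, 0) /
                                                   charFadeHalflife), 0)
    B[burned, ] <- pmax(B[burned, , drop = FALSE],
                        matrix(charFade, sum(burned), nd, byrow = TRUE))
    for (ci in unique(classVec[burned])) {
      sup <- fireSuppression(t, ev$time, ev$severity,
                             classes[[ci]]@phenology@decayHalflifeDays)
      rowsHit <- burned & classVec == ci
      G[rowsHit, ] <- G[rowsHit, , drop = FALSE] *
        matrix(sup, sum(rowsHit), nd, byrow = TRUE)
    }
  }

  ## quality layer: clouds and swath gaps
  quality <- matrix(QUALITY_VALID, np, nd)
  withSeed(childSeed(config@seed, 6L), {
    cloudFrac <- rbeta(nd, config@cloudBetaParams[1], config@cloudBetaParams[2])
    gapHit <- runif(nd) < config@gapProb
    for (j in seq_len(nd)) {
      if (cloudFrac[j] * np >= 1) {
        cl <- flattenGrid(randomRectangle(gr, gc, cloudFrac[j]))
        quality[cl, j] <- QUALITY_CLOUD
      }
      if (gapHit[j]) {
        gp <- flattenGrid(randomRectangle(gr, gc, runif(1, 0.10, 0.45)))
        quality[gp, j] <- QUALITY_NODATA
      }
    }
  })

  ## spectra: mixture -> char blend -> clouds -> noise
  vegBands <- vapply(classes, function(cl) cl@endmember, numeric(5))  # 5 x nclass
  bands <- setNames(vector("list", 5L), BAND_NAMES)
  noiseSeed <- childSeed(config@seed, 5L)
  withSeed(noiseSeed, {
    for (b in BAND_NAMES) {
      vb <- vegBands[b, classVec]
      R <- G * vb + (1 - G) * SOIL_ENDMEMBER[[b]]
      R <- (1 - B) * R + B * CHAR_ENDMEMBER[[b]]
      R[quality == QUALITY_CLOUD] <- CLOUD_REFLECTANCE[[b]]
      if (config@noiseSd > 0) {
        eps <- matrix(rnorm(np * nd, 0, config@noiseSd), np, nd)
        R <- if (config@noiseType == "additive") R + eps else R * (1 + eps)
      }
      R[quality == QUALITY_NODATA] <- NA_real_
      R <- clip01(R)
      dimnames(R) <- NULL
      bands[[b]] <- R
    }
  })

  pidx <- pixelIndexFrame(gr, gc)
  se <- SummarizedExperiment(
    assays = c(bands, list(quality = quality)),
    rowData = DataFrame(pixel_row = pidx$row, pixel_col = pidx$col),
    colData = DataFrame(date = as.Date(dates)))
  metadata(se) <- list(gridRows = gr, gridCols = gc,
                       geo = defaultGeo(gr, config@pixelSize))
  new("ReflectanceCube", se)
}

#' Simulate a complete synthetic scene
#'
#' Draws acquisition dates, rainfall, the landscape mosaic and the fire
#' schedule from the config's master seed, renders the reflectance cube, and
#' bundles everything with the ground truth. Identical config implies a
#' bit-identical scene.
#'
#' @param config a [SceneConfig-class]
#' @param classes cover-class list, default [defaultCoverClasses()]
#' @param fires optional [FireSchedule-class] overriding the seeded default
#'   (two rectangle burns at one- and two-thirds of the span)
#' @return a [SyntheticScene-class]
#' @examples
#' sc <- simulateScene(sceneConfig(gridRows = 8, gridCols = 8,
#'                                 startDate = "2020-01-01",
#'                                 endDate = "2021-01-01", seed = 1))
#' @export
simulateScene <- function(config, classes = defaultCoverClasses(),
                          fires = NULL) {
  stopifnot(is(config, "SceneConfig"))
  dates <- generateDates(config)
  rain <- simulateRainfall(c(config@startDate, config@endDate),
                           config@rainRatePerYear, config@rainMagnitudeMean,
                           seed = childSeed(config@seed, 2L))
  land <- makeLandscape(config@gridRows, config@gridCols,
                        seed = childSeed(config@seed, 3L))
  if (is.null(fires)) {
    spanDays <- as.numeric(config@endDate - config@startDate)
    events <- list()
    if (config@nFires > 0L) withSeed(childSeed(config@seed, 4L), {
      for (i in seq_len(config@nFires)) {
        events[[i]] <- list(
          time = spanDays * i / (config@nFires + 1) + runif(1, -30, 30),
          mask = randomRectangle(config@gridRows, config@gridCols,
                                 runif(1, 0.15, 0.35)),
          severity = runif(1, 0.5, 0.95))
      }
    })
    fires <- new("FireSchedule", origin = config@startDate, events = events)
  }
  cube <- renderReflectance(land$cover, classes, rain, fires, dates, config)
  truth <- matrix(as.integer(land$cover == match("buffel", names(classes))),
                  config@gridRows, config@gridCols)
  new("SyntheticScene", cube = cube, truth = truth, strata = land$strata,
      cover = land$cover, classes = classes, rainfall = rain, fire = fires,
      config = config)
}

#' Sample ground-truth waypoints from a scene
#'
#' Without-replacement pixel sample carrying coordinates (pixel centers),
#' the binary truth label and the stratum id. With `stratified = TRUE` and a
#' scalar `n`, allocation is proportional to stratum area (largest-remainder
#' rounding); `n` may instead be a vector of per-stratum counts, optionally
#' named by stratum id.
#'
#' @param scene a [SyntheticScene-class]
#' @param n total waypoint count, or per-stratum counts
#' @param stratified sample within strata?
#' @param seed integer seed
#' @return data.frame with columns x, y, label ("buffel"/"buffel_free"),
#'   stratum, pixel_row, pixel_col
#' @export
sampleWaypoints <- function(scene, n, stratified = TRUE, seed = 1L) {
  stopifnot(is(scene, "SyntheticScene"))
  gr <- scene@config@gridRows; gc <- scene@config@gridCols
  np <- gr * gc
  strataVec <- flattenGrid(scene@strata)
  truthVec <- flattenGrid(scene@truth)
  if (sum(n) > np)
    stop("requested more waypoints than pixels", call. = FALSE)

  pick <- integer(0)
  withSeed(seed, {
    if (!stratified) {
      pick <- sort(sample.int(np, sum(n)))
    } else {
      ids <- sort(unique(strataVec))
      counts <- if (length(n) == 1L) {
        sizes <- tabulate(match(strataVec, ids))
        raw <- n * sizes / np
        alloc <- floor(raw)
        rem <- n - sum(alloc)
        if (rem > 0) {
          extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
          alloc[extra] <- alloc[extra] + 1L
        }
        alloc
      } else if (!is.null(names(n))) {
        n[match(as.character(ids), names(n))]
      } else {
        if (length(n) != length(ids))
          stop("per-stratum counts must match the number of strata", call. = FALSE)
        n
      }
      for (i in seq_along(ids)) {
        avail <- which(strataVec == ids[i])
        if (counts[i] > length(avail))
          stop(sprintf("stratum %s has only %d pixels but %d waypoints requested",
                       ids[i], length(avail), counts[i]), call. = FALSE)
        pick <- c(pick, sample(avail, counts[i]))
      }
      pick <- sort(pick)
    }
  })
  pidx <- pixelIndexFrame(gr, gc)[pick, , drop = FALSE]
  ctr <- pixelCenters(pidx, geoMeta(scene@cube))
  data.frame(x = ctr$x, y = ctr$y,
             label = ifelse(truthVec[pick] == 1L, "buffel", "buffel_free"),
             stratum = strataVec[pick],
             pixel_row = pidx$row, pixel_col = pidx$col)
}
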