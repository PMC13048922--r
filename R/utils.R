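## Internal helpers: seeded evaluation, derived seeds, small assertions.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. All randomness in the package flows through
# this so that no function perturbs global RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# Deterministic child seed, kept below 2^31 - 1.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629L)
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf,
                             strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its valid range", name, x), call. = FALSE)
  invisible(x)
}

# row-major flattening: pixel j (1-based) of an R x C grid
pixelIndexFrame <- function(nrow, ncol) {
  j <- seq_len(nrow * ncol)
  data.frame(row = ((j - 1L) %/% ncol) + 1L,
             col = ((j - 1L) %% ncol) + 1L)
}

# grid coordinates of pixel centers under a top-left-origin geotransform
pixelCenters <- function(pixelIndex, geo) {
  list(x = geo$originX + (pixelIndex$col - 0.5) * geo$pixelSize,
       y = geo$originY - (pixelIndex$row - 0.5) * geo$pixelSize)
}

defaultGeo <- function(nrowGrid, pixelSize = 10) {
  list(originX = 0, originY = nrowGrid * pixelSize,
       pixelSize = pixelSize, crs = "local-metric")
}

# Nearest-pixel-center lookup. Coordinates exactly on a pixel boundary are
# equidistant from two centers; the documented tie-break takes the smaller
# row, then the smaller column.
coordsToPixels <- function(x, y, geo, gridRows, gridCols) {
  u <- (x - geo$originX) / geo$pixelSize   # column axis, 0 at left edge
  v <- (geo$originY - y) / geo$pixelSize   # row axis, 0 at top edge
  onEdge <- function(w) abs(w - round(w)) < 1e-9
  colOf <- function(w) {
    k <- if (onEdge(w)) round(w) else floor(w) + 1  # boundary -> smaller index
    as.integer(pmin(pmax(k, 1), gridCols))
  }
  rowOf <- function(w) {
    k <- if (onEdge(w)) round(w) else floor(w) + 1
    as.integer(pmin(pmax(k, 1), gridRows))
  }
  outside <- u < -1e-9 | u > gridCols + 1e-9 | v < -1e-9 | v > gridRows + 1e-9
  if (any(outside)) {
    i <- which(outside)[1L]
    stop(sprintf("waypoint (%g, %g) falls outside the raster extent", x[i], y[i]),
         call. = FALSE)
  }
  list(row = vapply(v, rowOf, integer(1)), col = vapply(u, colOf, integer(1)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## canonical band and index names
BAND_NAMES <- c("BLUE", "GREEN", "RED", "NIR", "SWIR1")
INDEX_NAMES <- c("EVI", "NBR", "NDVI", "NDWI")
## quality codes in the cube's "quality" assay
QUALITY_VALID <- 0L
QUALITY_CLOUD <- 1L
QUALITY_NODATA <- 2L
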