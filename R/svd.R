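## Truncated SVD of spatiotemporal matrices and feature assembly.

# Randomized truncated SVD by blocked subspace iteration with Gaussian test
# matrix, oversampling `p` beyond the requested rank, and an adaptive stop:
# iterate until the leading-k Ritz values and the leading-k left subspace
# stabilise. On matrices with decaying spectra (the production case) this
# converges in a few sweeps; on near-flat spectra it keeps iterating until
# the exact-oracle tolerance is met.
randomizedSVD <- function(M, k, oversample = 10L, tol = 1e-10, maxit = 400L,
                          seed = 1L) {
  n <- nrow(M); p <- ncol(M)
  l <- min(k + oversample, n, p)
  Q <- withSeed(seed, {
    Omega <- matrix(rnorm(p * l), p, l)
    qr.Q(qr(M %*% Omega))
  })
  dOld <- rep(Inf, k)
  Uk <- NULL
  for (it in seq_len(maxit)) {
    Q <- qr.Q(qr(crossprod(M, Q)))      # p x l
    Q <- qr.Q(qr(M %*% Q))              # n x l
    B <- crossprod(Q, M)                # l x p
    sv <- svd(B, nu = l, nv = 0)
    d <- sv$d[seq_len(k)]
    UkNew <- (Q %*% sv$u)[, seq_len(k), drop = FALSE]
    dConv <- max(abs(d - dOld) / pmax(d, .Machine$double.eps))
    sConv <- if (is.null(Uk)) Inf else {
      cosines <- svd(crossprod(Uk, UkNew), nu = 0, nv = 0)$d
      sqrt(max(0, 1 - min(cosines)^2))  # sin of the largest principal angle
    }
    dOld <- d; Uk <- UkNew
    if (dConv < tol && sConv < tol) break
  }
  B <- crossprod(Q, M)
  sv <- svd(B)
  list(d = sv$d[seq_len(k)],
       u = (Q %*% sv$u)[, seq_len(k), drop = FALSE],
       v = sv$v[, seq_len(k), drop = FALSE],
       iterations = it)
}

#' Truncated SVD of a spatiotemporal matrix
#'
#' Decomposes the dates x pixels matrix M ~ U S V': U columns are temporal
#' modes (one entry per date), V columns are spatial loadings (one entry per
#' pixel; these become classifier features). Variance fractions are
#' sigma_i^2 / sum(M^2), i.e. each component's share of the total squared
#' variation of the full (uncentred) matrix. Components are sign-normalised
#' (see [signNormalize()]).
#'
#' @param stm a [SpatioTemporalMatrix-class] or plain numeric matrix
#' @param k number of components to retain (<= min(dim))
#' @param method "exact" (LAPACK) or "randomized" (seeded subspace iteration)
#' @param seed seed for the randomized sketch
#' @param tol,maxit convergence controls for the randomized method
#' @return a [DecompositionResult-class]
#' @export
decomposeMatrix <- function(stm, k = 6L, method = c("exact", "randomized"),
                            seed = 1L, tol = 1e-10, maxit = 400L) {
  method <- match.arg(method)
  if (is(stm, "SpatioTemporalMatrix")) {
    M <- matrixValues(stm)
    meta <- list(indexName = stm@indexName, dates = stm@dates,
                 pixelIndex = stm@pixelIndex, geo = stm@geo,
                 gridRows = stm@gridRows, gridCols = stm@gridCols)
  } else {
    M <- as.matrix(stm)
    meta <- list(indexName = "matrix",
                 dates = as.Date("1970-01-01") + seq_len(nrow(M)) - 1L,
                 pixelIndex = data.frame(row = seq_len(ncol(M)),
                                         col = rep(1L, ncol(M))),
                 geo = defaultGeo(ncol(M)), gridRows = ncol(M), gridCols = 1L)
  }
  k <- as.integer(k)
  if (k < 1L || k > min(dim(M)))
    stop(sprintf("k = %d exceeds the rank bound min(%d, %d)", k,
                 nrow(M), ncol(M)), call. = FALSE)
  totalEnergy <- sum(M^2)
  if (method == "exact") {
    sv <- svd(M, nu = k, nv = k)
    d <- sv$d[seq_len(k)]; u <- sv$u; v <- sv$v
  } else {
    rs <- randomizedSVD(M, k, tol = tol, maxit = maxit, seed = seed)
    d <- rs$d; u <- rs$u; v <- rs$v
  }
  res <- new("DecompositionResult",
             singularValues = d, temporalModes = u, spatialLoadings = v,
             varianceFractions = if (totalEnergy > 0) d^2 / totalEnergy
                                 else rep(0, k),
             totalEnergy = totalEnergy, indexName = meta$indexName,
             dates = meta$dates, pixelIndex = meta$pixelIndex, geo = meta$geo,
             gridRows = as.integer(meta$gridRows),
             gridCols = as.integer(meta$gridCols), method = method)
  signNormalize(res)
}

#' Fix the sign ambiguity of SVD components
#'
#' Each singular-vector pair (u_i, v_i) is only determined up to a joint sign
#' flip; logistic coefficients over loadings are sign-sensitive, so a
#' canonical choice is needed. Convention: the maximum-absolute entry of each
#' temporal mode is made positive, flipping the paired spatial loading with
#' it. Idempotent; leaves the reconstruction U S V' unchanged.
#'
#' @param result a [DecompositionResult-class]
#' @return the result with canonical component signs
#' @export
signNormalize <- function(result) {
  stopifnot(is(result, "DecompositionResult"))
  u <- result@temporalModes; v <- result@spatialLoadings
  for (i in seq_len(ncol(u))) {
    m <- which.max(abs(u[, i]))
    if (u[m, i] < 0) {
      u[, i] <- -u[, i]
      v[, i] <- -v[, i]
    }
  }
  result@temporalModes <- u
  result@spatialLoadings <- v
  result
}

#' Assemble the per-pixel feature table
#'
#' Concatenates the retained spatial loadings of each index's decomposition
#' into one pixels x features matrix, columns named `<index>_<component>`
#' (ndvi_1 ... ndvi_6, evi_1, ...). With four indices and k = 6 this yields
#' the standard 24 input variables. All decompositions must share the same
#' pixel index. Loadings are the unit-norm right-singular-vector entries;
#' set `scaleBySingularValues = TRUE` to weight column i by sigma_i.
#'
#' @param results named list of [DecompositionResult-class], names = indices
#' @param retainedK components kept per index (default 6)
#' @param scaleBySingularValues weight loadings by their singular values?
#' @return a [FeatureTable-class]
#' @export
extractFeatures <- function(results, retainedK = 6L,
                            scaleBySingularValues = FALSE) {
  stopifnot(length(results) >= 1L)
  retainedK <- as.integer(retainedK)
  if (is.null(names(results)))
    names(results) <- vapply(results, indexName, character(1))
  ref <- results[[1]]
  cols <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    if (!identical(r@pixelIndex, ref@pixelIndex))
      stop("decompositions have mismatched pixel indices", call. = FALSE)
    if (length(r@singularValues) < retainedK)
      stop(sprintf("decomposition '%s' has fewer than %d components",
                   nm, retainedK), call. = FALSE)
    V <- spatialLoadings(r)[, seq_len(retainedK), drop = FALSE]
    if (scaleBySingularValues)
      V <- sweep(V, 2L, singularValues(r)[seq_len(retainedK)], `*`)
    colnames(V) <- paste0(tolower(nm), "_", seq_len(retainedK))
    cols[[nm]] <- V
  }
  values <- do.call(cbind, cols)
  ## canonical column order follows the order the indices were supplied in;
  ## rows are pixels in row-major grid order
  new("FeatureTable", values = values, pixelIndex = ref@pixelIndex,
      geo = ref@geo, gridRows = ref@gridRows, gridCols = ref@gridCols,
      retainedK = retainedK, indices = tolower(names(results)))
}

#' Look up features at ground-truth waypoints
#'
#' Nearest-pixel-center lookup of each waypoint's feature row. Waypoints on a
#' pixel boundary resolve to the smaller row, then smaller column. Multiple
#' waypoints falling in one pixel are deduplicated with a warning, keeping
#' the first.
#'
#' @param table a [FeatureTable-class]
#' @param waypoints data.frame with columns x, y, label and optionally
#'   stratum (see [sampleWaypoints()])
#' @return data.frame: pixel_row, pixel_col, label (0/1 where 1 = buffel),
#'   stratum (if present), then the feature columns
#' @export
featuresAtWaypoints <- function(table, waypoints) {
  stopifnot(is(table, "FeatureTable"))
  need <- c("x", "y", "label")
  if (!all(need %in% names(waypoints)))
    stop("waypoints must have columns x, y, label", call. = FALSE)
  gd <- gridDims(table)
  px <- coordsToPixels(waypoints$x, waypoints$y, geoMeta(table),
                       gd["rows"], gd["cols"])
  j <- (px$row - 1L) * gd[["cols"]] + px$col
  dup <- duplicated(j)
  if (any(dup)) {
    warning(sprintf("%d waypoints share a pixel with an earlier one; keeping the first of each",
                    sum(dup)))
    waypoints <- waypoints[!dup, , drop = FALSE]
    px <- lapply(px, `[`, !dup)
    j <- j[!dup]
  }
  lab <- waypoints$label
  if (!is.numeric(lab)) lab <- as.integer(lab %in% c("buffel", "1", "TRUE"))
  out <- data.frame(pixel_row = px$row, pixel_col = px$col, label = lab)
  if (!is.null(waypoints$stratum)) out$stratum <- waypoints$stratum
  cbind(out, as.data.frame(featureMatrix(table)[j, , drop = FALSE]))
}
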