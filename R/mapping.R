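## Probability surfaces, occurrence maps and landscape-stratum summaries.

#' Project a fitted logistic model onto the pixel grid
#'
#' Per pixel: Lin = beta_0 + sum(beta_i x_i) over the model's selected
#' features, mapped through the logistic function. The default "standard"
#' convention is the rising logistic P = 1/(1 + exp(-Lin));
#' `logitSign = "printed"` applies P = 1/(1 + exp(Lin)), which inverts all
#' probabilities and is provided only for comparison with reports that
#' typeset the transform that way.
#'
#' @param model a [LogisticMapModel-class]
#' @param table a [FeatureTable-class] whose columns cover the model's
#'   selected features
#' @param logitSign "standard" (default) or "printed"
#' @return a [ProbabilitySurface-class]
#' @export
predictSurface <- function(model, table, logitSign = c("standard", "printed")) {
  logitSign <- match.arg(logitSign)
  stopifnot(is(model, "LogisticMapModel"), is(table, "FeatureTable"))
  p <- scoreProbability(model, featureMatrix(table))
  if (logitSign == "printed") {
    message("using the 'printed' logistic convention P = 1/(1 + exp(Lin)): ",
            "probabilities are inverted relative to the standard rising logistic")
    p <- 1 - p
  }
  gd <- gridDims(table)
  grid <- matrix(p, nrow = gd[["rows"]], ncol = gd[["cols"]], byrow = TRUE)
  new("ProbabilitySurface", prob = grid, geo = geoMeta(table),
      modelId = sprintf("logistic[%s]",
                        paste(selectedFeatures(model), collapse = "+")))
}

#' Threshold a probability surface into an occurrence map
#'
#' Occurrence is `P >= t` (the boundary is included, so t = 0.5 marks a
#' pixel with P exactly 0.5 as occupied). The occupied-pixel count is
#' attached as attribute `occupied`.
#'
#' @param surface a [ProbabilitySurface-class]
#' @param t probability threshold in (0, 1)
#' @return integer grid matrix (1 = occurrence) with attribute `occupied`
#' @export
thresholdMap <- function(surface, t = 0.5) {
  stopifnot(is(surface, "ProbabilitySurface"))
  stopifnot_scalar(t, "t", min = 0, max = 1, strict_min = TRUE,
                   strict_max = TRUE)
  occ <- matrix(as.integer(probabilityGrid(surface) >= t),
                nrow(surface@prob), ncol(surface@prob))
  attr(occ, "occupied") <- sum(occ)
  occ
}

#' Stratum-level occurrence summary
#'
#' Per landscape stratum: pixel count, area, and the fractions of stratum
#' pixels with P >= 0.50 (p50) and P >= 0.75 (p75). Fractions are of the
#' stratum's own area. Strata with zero pixels are omitted with a warning.
#'
#' @param surface a [ProbabilitySurface-class]
#' @param strata integer grid matrix of stratum ids, conforming to the surface
#' @param strataNames optional names, indexed by stratum id
#' @return data.frame: stratum, name, n_pixels, area_km2, p50, p75
#' @export
strataSummary <- function(surface, strata, strataNames = NULL) {
  stopifnot(is(surface, "ProbabilitySurface"))
  P <- probabilityGrid(surface)
  if (!identical(dim(strata), dim(P)))
    stop("strata grid does not conform to the surface", call. = FALSE)
  pixelAreaKm2 <- (surface@geo$pixelSize / 1000)^2
  ids <- sort(unique(as.vector(strata)))
  rows <- lapply(ids, function(s) {
    inS <- strata == s
    n <- sum(inS)
    if (n == 0L) {
      warning(sprintf("stratum %s has no pixels; omitted", s))
      return(NULL)
    }
    data.frame(stratum = s,
               name = if (!is.null(strataNames)) strataNames[[s]] else as.character(s),
               n_pixels = n, area_km2 = n * pixelAreaKm2,
               p50 = mean(P[inS] >= 0.50), p75 = mean(P[inS] >= 0.75))
  })
  do.call(rbind, rows)
}

#' Stratum-level accuracy at ground-truth waypoints
#'
#' Groups waypoints by stratum and computes sensitivity, specificity and
#' accuracy of the thresholded surface against the waypoint labels within
#' each group (plus a pooled "all" row). Strata with no waypoints are
#' omitted.
#'
#' @param surface a [ProbabilitySurface-class]
#' @param waypoints data.frame with x, y, label, stratum
#' @param t probability threshold
#' @return data.frame: stratum, n_waypoints, specificity, sensitivity,
#'   accuracy
#' @export
strataAccuracy <- function(surface, waypoints, t = 0.5) {
  stopifnot(is(surface, "ProbabilitySurface"))
  need <- c("x", "y", "label", "stratum")
  if (!all(need %in% names(waypoints)))
    stop("waypoints must have columns x, y, label, stratum", call. = FALSE)
  P <- probabilityGrid(surface)
  px <- coordsToPixels(waypoints$x, waypoints$y, surface@geo,
                       nrow(P), ncol(P))
  scores <- P[cbind(px$row, px$col)]
  pred <- as.integer(scores >= t)
  y <- normalizeLabels(waypoints$label)
  groups <- c(split(seq_along(y), waypoints$stratum),
              list(all = seq_along(y)))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    m <- confusionMetrics(pred[idx], y[idx])
    data.frame(stratum = g, n_waypoints = length(idx),
               specificity = m[["specificity"]],
               sensitivity = m[["sensitivity"]],
               accuracy = m[["accuracy"]])
  })
  do.call(rbind, rows)
}
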