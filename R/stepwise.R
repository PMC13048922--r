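## Forward-stepwise logistic regression under BIC.

# Binomial deviance-based BIC of a design matrix (intercept included as the
# first column). Uses the fit's rank, not its column count, so aliased
# (collinear) columns do not earn a parameter penalty.
glmBIC <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  list(bic = fit$deviance + log(length(y)) * fit$rank, fit = fit)
}

# Ridge-penalised logistic regression by IRLS; the fallback when maximum
# likelihood is degenerate under perfect separation. Non-intercept columns
# are standardised internally (SVD loadings live on a ~1/sqrt(n_pixels)
# scale, so a raw-scale penalty would crush the coefficients and wreck the
# calibration of the 0.5 decision boundary); the small penalty applies on
# the standardised scale and coefficients are mapped back.
ridgeLogistic <- function(X, y, lambda = 1e-3, maxit = 200L, tol = 1e-10) {
  p <- ncol(X)
  ctr <- c(0, colMeans(X[, -1L, drop = FALSE]))
  scl <- c(1, apply(X[, -1L, drop = FALSE], 2L, sd))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  Xs[, 1L] <- 1
  pen <- c(0, rep(lambda, p - 1L))
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(Xs %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xs * w, Xs) + diag(pen, p)
    g <- crossprod(Xs, y - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  out <- beta / scl
  out[1L] <- beta[1L] - sum(beta[-1L] * ctr[-1L] / scl[-1L])
  out
}

looksSeparated <- function(fit) {
  isTRUE(fit$boundary) || !isTRUE(fit$converged) ||
    any(abs(fit$coefficients) > 25, na.rm = TRUE)
}

#' Forward-stepwise logistic regression under BIC
#'
#' Starts from the intercept-only model and repeatedly adds the candidate
#' feature whose inclusion gives the lowest BIC (deviance + log(n) x
#' parameters), stopping when no addition strictly lowers BIC. Ties resolve
#' to the first feature in canonical column order, making the procedure
#' deterministic. Constant-valued candidates are dropped with a warning.
#' Under perfect separation the selected model is refit with a small ridge
#' penalty and flagged in the metadata.
#'
#' @param features numeric matrix (or data.frame) with named columns
#' @param labels binary labels: 0/1, logical, or "buffel"/"buffel_free"
#' @param criterion only "BIC" is implemented
#' @param maxSteps cap on the number of entered features
#' @return a [LogisticMapModel-class]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- rbinom(200, 1, plogis(3 * x[, 2]))
#' selectedFeatures(stepwiseLogistic(x, y))
#' @export
stepwiseLogistic <- function(features, labels, criterion = "BIC",
                             maxSteps = Inf) {
  if (!identical(criterion, "BIC"))
    stop("only the BIC criterion is implemented", call. = FALSE)
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("features must have column names", call. = FALSE)
  y <- normalizeLabels(labels)
  if (length(y) != nrow(X)) stop("labels must match feature rows", call. = FALSE)
  if (min(table(y)) < 2L)
    stop("need at least 2 observations per class", call. = FALSE)
  n <- length(y)

  constant <- apply(X, 2L, function(col) diff(range(col)) == 0)
  if (any(constant)) {
    warning(sprintf("dropping constant candidate feature(s): %s",
                    paste(colnames(X)[constant], collapse = ", ")))
    X <- X[, !constant, drop = FALSE]
  }
  candidates <- colnames(X)

  selected <- character(0)
  intOnly <- glmBIC(matrix(1, n, 1L), y)
  bicPath <- intOnly$bic
  currentBIC <- intOnly$bic
  currentFit <- intOnly$fit
  while (length(selected) < min(maxSteps, length(candidates))) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trialBIC <- vapply(remaining, function(f) {
      glmBIC(cbind(1, X[, c(selected, f), drop = FALSE]), y)$bic
    }, numeric(1))
    best <- which.min(trialBIC)   # ties resolve to the first in column order
    if (trialBIC[best] >= currentBIC) break   # strict decrease required
    selected <- c(selected, remaining[best])
    currentBIC <- trialBIC[best]
    bicPath <- c(bicPath, currentBIC)
    currentFit <- glmBIC(cbind(1, X[, selected, drop = FALSE]), y)$fit
  }

  separated <- looksSeparated(currentFit)
  if (separated && length(selected)) {
    beta <- ridgeLogistic(cbind(1, X[, selected, drop = FALSE]), y)
  } else {
    beta <- currentFit$coefficients
    beta[is.na(beta)] <- 0
  }
  coefs <- if (length(selected)) setNames(beta[-1L], selected)
           else setNames(numeric(0), character(0))
  new("LogisticMapModel",
      intercept = unname(beta[1L]), coefficients = coefs,
      selectedFeatures = selected, candidateFeatures = candidates,
      bicPath = bicPath,
      metadata = list(criterion = "BIC", n = n,
                      separation_ridge = separated,
                      dropped_constant = colnames(features)[constant]))
}

# Accepts 0/1, logical, factor, or the waypoint labels "buffel"/"buffel_free".
normalizeLabels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    y <- as.integer(labels %in% c("buffel", "1", "TRUE", "yes"))
  } else {
    y <- as.integer(labels)
  }
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  y
}

#' @rdname scoreProbability
setMethod("scoreProbability", "LogisticMapModel", function(model, features, ...) {
  X <- as.matrix(features)
  missing <- setdiff(model@selectedFeatures, colnames(X))
  if (length(missing))
    stop(sprintf("feature column(s) missing from input: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lin <- rep(model@intercept, nrow(X))
  if (length(model@selectedFeatures))
    lin <- lin + drop(X[, model@selectedFeatures, drop = FALSE] %*%
                        model@coefficients)
  plogis(lin)
})
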