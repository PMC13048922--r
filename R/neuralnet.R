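## The neural-net comparator: a fixed input -> 3 (tanh) -> 1 (sigmoid)
## architecture fit by full-batch quasi-Newton (BFGS) minimisation of the
## cross-entropy with a small weight-decay term, analytic gradients, seeded
## initialisation and a few seeded restarts keeping the best optimum.

nnUnpack <- function(theta, nf, nh) {
  i1 <- nf * nh
  list(W1 = matrix(theta[seq_len(i1)], nf, nh),
       b1 = theta[i1 + seq_len(nh)],
       W2 = theta[i1 + nh + seq_len(nh)],
       b2 = theta[i1 + 2L * nh + 1L])
}

nnForward <- function(pars, X) {
  Z <- tanh(sweep(X %*% pars$W1, 2L, pars$b1, `+`))
  list(Z = Z, p = plogis(drop(Z %*% pars$W2) + pars$b2))
}

nnLoss <- function(theta, X, y, nh, decay) {
  pars <- nnUnpack(theta, ncol(X), nh)
  fw <- nnForward(pars, X)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p)) +
    decay * (sum(pars$W1^2) + sum(pars$W2^2))
}

nnGrad <- function(theta, X, y, nh, decay) {
  n <- nrow(X)
  pars <- nnUnpack(theta, ncol(X), nh)
  fw <- nnForward(pars, X)
  dOut <- (fw$p - y) / n                       # d loss / d (output logit)
  gW2 <- drop(crossprod(fw$Z, dOut)) + 2 * decay * pars$W2
  gb2 <- sum(dOut)
  dHidden <- (dOut %o% pars$W2) * (1 - fw$Z^2)  # n x nh
  gW1 <- crossprod(X, dHidden) + 2 * decay * pars$W1
  gb1 <- colSums(dHidden)
  c(as.vector(gW1), gb1, gW2, gb2)
}

#' Fit the tanh neural-net comparator
#'
#' Trains a single-hidden-layer network (3 tanh nodes, sigmoid output) on all
#' supplied features by full-batch BFGS on the cross-entropy with weight
#' decay `decay`, to gradient tolerance ~1e-6. Initial weights are seeded;
#' `restarts` independent seeded starts are tried and the best optimum kept,
#' so refitting with the same seed reproduces identical parameters.
#'
#' @param features numeric matrix with named columns
#' @param labels binary labels (as in [stepwiseLogistic()])
#' @param hiddenNodes hidden-layer width (default 3)
#' @param seed integer seed for initialisation
#' @param decay L2 weight-decay coefficient
#' @param restarts number of seeded random starts
#' @param maxit BFGS iteration cap per start
#' @return a [NeuralNetModel-class]
#' @export
fitNeuralNet <- function(features, labels, hiddenNodes = 3L, seed = 1L,
                         decay = 1e-4, restarts = 3L, maxit = 2000L) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stop("features must have column names", call. = FALSE)
  y <- normalizeLabels(labels)
  nf <- ncol(X); nh <- as.integer(hiddenNodes)
  npar <- nf * nh + nh + nh + 1L
  best <- NULL
  for (r in seq_len(restarts)) {
    theta0 <- withSeed(childSeed(seed, r), runif(npar, -0.5, 0.5))
    opt <- optim(theta0, nnLoss, nnGrad, X = X, y = y, nh = nh, decay = decay,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  converged <- best$convergence == 0L
  if (!converged)
    warning("neural net did not fully converge; returning the best iterate")
  pars <- nnUnpack(best$par, nf, nh)
  new("NeuralNetModel", W1 = pars$W1, b1 = pars$b1, W2 = pars$W2, b2 = pars$b2,
      featureNames = colnames(X),
      spec = list(hidden_layers = 1L, hidden_nodes = nh, activation = "tanh",
                  output = "sigmoid"),
      metadata = list(converged = converged, loss = best$value,
                      optimizer = "BFGS (full batch)", decay = decay,
                      restarts = restarts, seed = seed))
}

#' @rdname scoreProbability
setMethod("scoreProbability", "NeuralNetModel", function(model, features, ...) {
  X <- as.matrix(features)
  missing <- setdiff(model@featureNames, colnames(X))
  if (length(missing))
    stop(sprintf("feature column(s) missing from input: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  X <- X[, model@featureNames, drop = FALSE]
  nnForward(list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2),
            X)$p
})
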