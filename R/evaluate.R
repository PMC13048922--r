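## Classifier evaluation: ROC-AUC, confusion metrics, threshold selection,
## and the repeated stratified-split bootstrap protocol.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via midranks: the
#' probability a random positive scores above a random negative, with half
#' credit for ties. Equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels binary labels
#' @return AUC in \[0,1\]
#' @examples
#' rocAuc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  y <- normalizeLabels(labels)
  if (length(scores) != length(y))
    stop("scores and labels must have equal length", call. = FALSE)
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Sensitivity, specificity and accuracy of binary predictions
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/N. A metric with a zero denominator (e.g. sensitivity
#' with no true positives in the reference) is reported as NA, never as 0.
#'
#' @param predicted binary predicted labels
#' @param labels binary reference labels
#' @return named numeric: sensitivity, specificity, accuracy
#' @export
confusionMetrics <- function(predicted, labels) {
  p <- normalizeLabels(predicted)
  y <- normalizeLabels(labels)
  if (length(p) != length(y))
    stop("predicted and labels must have equal length", call. = FALSE)
  tp <- sum(p == 1L & y == 1L); fn <- sum(p == 0L & y == 1L)
  tn <- sum(p == 0L & y == 0L); fp <- sum(p == 1L & y == 0L)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(y))
}

#' Select a probability threshold
#'
#' Sweeps the observed score cut-points (prediction rule: score >= t) and
#' returns the threshold maximising Youden's J = sensitivity + specificity
#' - 1 (default) or minimising the misclassification count. Ties resolve to
#' the cut-point nearest 0.5. Degenerate all-equal scores return 0.5 with a
#' warning.
#'
#' @param scores numeric scores in \[0,1\]
#' @param labels binary labels
#' @param objective "youden" or "misclass"
#' @return the selected threshold
#' @export
selectThreshold <- function(scores, labels, objective = c("youden", "misclass")) {
  objective <- match.arg(objective)
  y <- normalizeLabels(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to select a threshold", call. = FALSE)
  cuts <- sort(unique(scores))
  if (length(cuts) == 1L) {
    warning("all scores identical; returning threshold 0.5")
    return(0.5)
  }
  objective_value <- vapply(cuts, function(t) {
    m <- confusionMetrics(as.integer(scores >= t), y)
    if (objective == "youden") m["sensitivity"] + m["specificity"] - 1
    else -sum((scores >= t) != (y == 1L))
  }, numeric(1))
  best <- which(objective_value >= max(objective_value, na.rm = TRUE) - 1e-12)
  cuts[best][which.min(abs(cuts[best] - 0.5))]
}

#' Bootstrap evaluation by repeated stratified splits
#'
#' Implements the training protocol of repeated stratified random splits:
#' per bootstrap, two-thirds of the observations (per class) train the model
#' and one-third validate it; sensitivity, specificity, accuracy (at
#' `threshold`) and ROC-AUC are recorded for both roles, and the report
#' carries each metric's mean and standard error (SD over bootstraps /
#' sqrt(n_boot)). A split leaving a single-class validation set is redrawn
#' (seeded) and the retry counted.
#'
#' @param fitter function(features, labels) returning a model understood by
#'   [scoreProbability()] — e.g. `stepwiseLogistic`, or a closure over
#'   [fitNeuralNet()]
#' @param features numeric matrix with named columns
#' @param labels binary labels
#' @param nBoot number of bootstrap splits (>= 2), default 10
#' @param trainFraction training share, default 2/3
#' @param seed integer seed driving all splits
#' @param threshold probability cut for the confusion metrics
#' @param modelLabel label stored in the report
#' @return an [EvaluationReport-class]
#' @export
bootstrapEvaluate <- function(fitter, features, labels, nBoot = 10L,
                              trainFraction = 2 / 3, seed = 1L,
                              threshold = 0.5, modelLabel = "model") {
  X <- as.matrix(features)
  y <- normalizeLabels(labels)
  nBoot <- as.integer(nBoot)
  if (nBoot < 2L) stop("nBoot must be at least 2", call. = FALSE)
  stopifnot_scalar(trainFraction, "trainFraction", min = 0, max = 1,
                   strict_min = TRUE, strict_max = TRUE)
  metricNames <- c("sensitivity", "specificity", "accuracy", "auc")
  acc <- list(training = matrix(NA_real_, nBoot, 4L,
                                dimnames = list(NULL, metricNames)),
              validation = matrix(NA_real_, nBoot, 4L,
                                  dimnames = list(NULL, metricNames)))
  retries <- 0L
  for (b in seq_len(nBoot)) {
    attempt <- 0L
    repeat {
      trainIdx <- withSeed(childSeed(seed, b * 131L + attempt), {
        unlist(lapply(split(seq_along(y), y), function(idx)
          sample(idx, round(trainFraction * length(idx)))))
      })
      validIdx <- setdiff(seq_along(y), trainIdx)
      if (length(unique(y[validIdx])) == 2L &&
          length(unique(y[trainIdx])) == 2L) break
      attempt <- attempt + 1L
      retries <- retries + 1L
      if (attempt > 100L) stop("could not draw a two-class split", call. = FALSE)
    }
    model <- fitter(X[trainIdx, , drop = FALSE], y[trainIdx])
    for (role in c("training", "validation")) {
      idx <- if (role == "training") trainIdx else validIdx
      s <- scoreProbability(model, X[idx, , drop = FALSE])
      m <- confusionMetrics(as.integer(s >= threshold), y[idx])
      acc[[role]][b, ] <- c(m, auc = rocAuc(s, y[idx]))
    }
  }
  rows <- do.call(rbind, lapply(names(acc), function(role) {
    data.frame(role = role, metric = metricNames,
               mean = colMeans(acc[[role]]),
               se = apply(acc[[role]], 2L, sd) / sqrt(nBoot),
               row.names = NULL)
  }))
  new("EvaluationReport", metrics = rows, nBoot = nBoot,
      trainFraction = trainFraction,
      metadata = list(model = modelLabel, resplit_retries = retries,
                      seed = seed, threshold = threshold,
                      per_boot = acc))
}

#' Write evaluation reports as a CSV table
#'
#' One row per model x split role; specificity and sensitivity rendered in
#' percent and accuracy/AUC on the 0-1 scale, each as mean and SE columns.
#'
#' @param reports an [EvaluationReport-class] or list of them
#' @param path output CSV path
#' @return the written data.frame, invisibly
#' @export
writeEvaluationReport <- function(reports, path) {
  if (is(reports, "EvaluationReport")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(r) {
    m <- r@metrics
    wide <- function(metric, scale = 1) {
      sub <- m[m$metric == metric, ]
      data.frame(role = sub$role, mean = sub$mean * scale, se = sub$se * scale)
    }
    sp <- wide("specificity", 100); sn <- wide("sensitivity", 100)
    ac <- wide("accuracy"); au <- wide("auc")
    data.frame(model = r@metadata$model, role = sp$role,
               specificity_pct_mean = sp$mean, specificity_pct_se = sp$se,
               sensitivity_pct_mean = sn$mean, sensitivity_pct_se = sn$se,
               accuracy_mean = ac$mean, accuracy_se = ac$se,
               auc_mean = au$mean, auc_se = au$se)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
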