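# Stepwise-BIC logistic regression, the tanh neural net, and evaluation.

simLogit <- function(n, p = 24, beta = NULL, seed = 1) {
  phenocube:::withSeed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    lin <- if (is.null(beta)) rep(0, n)
           else drop(X[, names(beta), drop = FALSE] %*% beta)
    y <- rbinom(n, 1, plogis(lin))
    list(X = X, y = y)
  })
}

test_that("stepwise selection finds the true driver first", {
  d <- simLogit(400, beta = c(f05 = 2.5), seed = 3)
  m <- stepwiseLogistic(d$X, d$y)
  expect_equal(selectedFeatures(m)[1], "f05")
  expect_gt(coef(m)[["f05"]], 0)
  # BIC strictly improves along the accepted path
  expect_true(all(diff(m@bicPath) < 0))
})

test_that("stepwise is conservative under the null", {
  # with 24 spurious candidates at n = 200 the best-of-24 score statistic
  # clears the log(n) BIC penalty occasionally, so an entry or two can
  # happen; models should still stay very small and mostly empty
  picks <- vapply(1:10, function(s) {
    d <- simLogit(200, seed = 100 + s)
    length(selectedFeatures(stepwiseLogistic(d$X, d$y)))
  }, numeric(1))
  expect_gte(mean(picks == 0), 0.5)
  expect_lte(mean(picks), 1)
  expect_lte(max(picks), 3)   # tiny relative to the 24 candidates
})

test_that("intercept-only fit on balanced labels gives a zero intercept", {
  X <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "junk"))
  y <- rep(c(0L, 1L), 50)
  m <- stepwiseLogistic(X, y, maxSteps = 0)
  expect_equal(m@intercept, 0, tolerance = 1e-9)
  expect_length(selectedFeatures(m), 0L)
})

test_that("duplicated and constant candidates are handled", {
  d <- simLogit(500, beta = c(f03 = 3), seed = 5)
  X <- cbind(d$X, f03_copy = d$X[, "f03"])
  m <- stepwiseLogistic(X, d$y)
  expect_true("f03" %in% selectedFeatures(m))
  expect_false("f03_copy" %in% selectedFeatures(m))   # no BIC gain, never enters

  Xc <- cbind(d$X, flat = 1)
  expect_warning(mc <- stepwiseLogistic(Xc, d$y), "constant")
  expect_false("flat" %in% mc@candidateFeatures)
})

test_that("perfect separation falls back to a flagged ridge fit", {
  X <- matrix(c(rnorm(50, -3), rnorm(50, 3)), 100, 1,
              dimnames = list(NULL, "x"))
  y <- rep(c(0L, 1L), each = 50)
  m <- stepwiseLogistic(X, y)
  expect_true(m@metadata$separation_ridge)
  expect_true(all(is.finite(coef(m))))
  expect_gt(mean((scoreProbability(m, X) >= 0.5) == y), 0.99)
})

test_that("AUC equals pairwise concordance, with half credit for ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(rocAuc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")

  # rank implementation vs the O(n^2) oracle, including heavy ties
  for (s in 1:20) {
    sc <- phenocube:::withSeed(s, round(runif(150), 2))
    lb <- phenocube:::withSeed(1000 + s, rbinom(150, 1, 0.4))
    if (length(unique(lb)) < 2) next
    expect_equal(rocAuc(sc, lb), bruteAuc(sc, lb), tolerance = 1e-12)
  }

  # independent cross-check against pROC on one dataset
  sc <- phenocube:::withSeed(77, runif(200))
  lb <- phenocube:::withSeed(78, rbinom(200, 1, 0.5))
  expect_equal(rocAuc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("confusion metrics match hand arithmetic and guard denominators", {
  expect_equal(unname(confusionMetrics(c(1, 0), c(1, 0))), c(1, 1, 1))
  pred <- c(rep(1, 9), rep(0, 1), rep(0, 8), rep(1, 2))
  truth <- c(rep(1, 10), rep(0, 10))
  expect_equal(unname(confusionMetrics(pred, truth)), c(0.9, 0.8, 0.85))
  m <- confusionMetrics(c(0, 1), c(0, 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_equal(m[["specificity"]], 0.5)
})

test_that("threshold selection maximises Youden's J with sane tie-breaks", {
  # perfectly separated at 0.3 / 0.7: the separating cut-point is returned
  expect_equal(selectThreshold(c(0.3, 0.3, 0.7, 0.7), c(0, 0, 1, 1)), 0.7)
  expect_warning(t0 <- selectThreshold(rep(0.4, 10), rep(c(0, 1), 5)),
                 "identical")
  expect_equal(t0, 0.5)
  # symmetric overlapping score distributions: threshold near 0.5
  sc <- phenocube:::withSeed(31, c(rnorm(3000, 0.6, 0.1), rnorm(3000, 0.4, 0.1)))
  lb <- rep(c(1, 0), each = 3000)
  expect_lt(abs(selectThreshold(sc, lb) - 0.5), 0.03)
})

test_that("the tanh net separates XOR structure a logistic model cannot", {
  d <- phenocube:::withSeed(8, {
    X <- matrix(sample(0:1, 800, TRUE), 400, 2,
                dimnames = list(NULL, c("a", "b")))
    y <- as.integer(xor(X[, 1], X[, 2]))
    X <- X + matrix(rnorm(800, 0, 0.05), 400, 2)
    list(X = X, y = y)
  })
  nn <- fitNeuralNet(d$X, d$y, seed = 2)
  expect_gt(mean((scoreProbability(nn, d$X) >= 0.5) == d$y), 0.9)
  lr <- stepwiseLogistic(d$X, d$y)
  expect_lte(mean((scoreProbability(lr, d$X) >= 0.5) == d$y), 0.65)

  # linearly separable toy set: full training accuracy
  ds <- simLogit(100, p = 2, seed = 12)
  ys <- as.integer(ds$X[, 1] > 0)
  nn2 <- fitNeuralNet(ds$X, ys, seed = 3)
  expect_equal(mean((scoreProbability(nn2, ds$X) >= 0.5) == ys), 1)

  # seeded refits reproduce identical parameters
  nn3 <- fitNeuralNet(d$X, d$y, seed = 2)
  expect_identical(nn@W1, nn3@W1)
  expect_identical(nn@W2, nn3@W2)
})

test_that("bootstrap evaluation reports exact limits and is deterministic", {
  d <- simLogit(300, beta = c(f01 = 3, f02 = -2), p = 4, seed = 21)

  # a perfect scorer: every metric 1 with zero SE
  oracleModel <- new("LogisticMapModel", intercept = -500,
                     coefficients = c(truth = 1000),
                     selectedFeatures = "truth", candidateFeatures = "truth",
                     bicPath = 0, metadata = list())
  Xp <- cbind(d$X, truth = d$y)
  rep1 <- bootstrapEvaluate(function(x, y) oracleModel, Xp, d$y,
                            nBoot = 5, seed = 9)
  expect_equal(rep1@metrics$mean, rep(1, 8))
  expect_equal(rep1@metrics$se, rep(0, 8))

  # an uninformative constant scorer: tie-credit AUC is exactly 0.5
  coinModel <- new("LogisticMapModel", intercept = 0,
                   coefficients = setNames(numeric(0), character(0)),
                   selectedFeatures = character(0),
                   candidateFeatures = "truth", bicPath = 0,
                   metadata = list())
  rep2 <- bootstrapEvaluate(function(x, y) coinModel, Xp, d$y,
                            nBoot = 5, seed = 9)
  auc <- rep2@metrics[rep2@metrics$metric == "auc" &
                        rep2@metrics$role == "validation", ]
  expect_equal(auc$mean, 0.5)

  # same seed, same report
  fitter <- function(x, y) stepwiseLogistic(x, y)
  r1 <- bootstrapEvaluate(fitter, d$X, d$y, nBoot = 4, seed = 33)
  r2 <- bootstrapEvaluate(fitter, d$X, d$y, nBoot = 4, seed = 33)
  expect_identical(r1@metrics, r2@metrics)
  expect_error(bootstrapEvaluate(fitter, d$X, d$y, nBoot = 1), "at least 2")
})
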