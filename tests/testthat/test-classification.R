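separable2d <- function(n = 100, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n, gap / 2), n / 2, 2),
             matrix(rnorm(n, -gap / 2), n / 2, 2))
  list(X = X, y = rep(c(1L, 0L), each = n / 2))
}

allKinds <- c("svm", "logistic", "naive_bayes", "decision_tree",
              "random_forest")

test_that("metrics match confusion-matrix arithmetic and conventions", {
  expect_equal(unname(evaluateMetrics(c(1, 0, 1, 0), c(1, 0, 1, 0))),
               c(1, 1, 1, 1))
  # TP=3, FP=1, FN=1, TN=5
  yT <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  yP <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(unname(evaluateMetrics(yT, yP)), c(0.8, 0.75, 0.75, 0.75))
  # no predicted positives while positives exist
  expect_equal(unname(evaluateMetrics(c(1, 1, 0), c(0, 0, 0))),
               c(1 / 3, 0, 0, 0))
  expect_error(evaluateMetrics(c(1, 0), c(1)), "length")
  expect_error(evaluateMetrics(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics agree with a brute-force oracle on random labelings", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    yT <- sample(0:1, n, replace = TRUE)
    yP <- sample(0:1, n, replace = TRUE)
    m <- evaluateMetrics(yT, yP)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_len(n)) {
      if (yT[j] == 1 && yP[j] == 1) tp <- tp + 1
      if (yT[j] == 0 && yP[j] == 1) fp <- fp + 1
      if (yT[j] == 1 && yP[j] == 0) fn <- fn + 1
      if (yT[j] == 0 && yP[j] == 0) tn <- tn + 1
    }
    expect_equal(unname(m["accuracy"]), (tp + tn) / n)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_equal(unname(m["precision"]), p)
    expect_equal(unname(m["recall"]), r)
    # F1 is the harmonic mean of precision and recall
    expect_equal(unname(m["f1"]),
                 if (p + r > 0) 2 / (1 / p + 1 / r) else 0)
  }
})

test_that("training validates labels and features", {
  d <- separable2d()
  expect_error(trainClassifier(d$X, rep(1L, nrow(d$X))), "both classes")
  bad <- d$X; bad[3, 1] <- NaN
  expect_error(trainClassifier(bad, d$y), "NaN")
  expect_error(trainClassifier(d$X, d$y[-1]), "one label")
  expect_error(classifierConfig(C = -1), "C must")
})

test_that("every classifier kind solves a linearly separable problem", {
  d <- separable2d(n = 120, gap = 6, seed = 52)
  for (k in allKinds) {
    m <- trainClassifier(d$X, d$y, classifierConfig(k))
    expect_equal(mean(predict(m, d$X) == d$y), 1,
                 info = k, tolerance = 0.01)
    expect_true(all(predict(m, d$X) %in% c(0L, 1L)))
  }
})

test_that("well-separated classes cross-validate above 0.95 for all kinds", {
  d <- separable2d(n = 200, gap = 4, seed = 53)
  for (k in allKinds) {
    r <- crossValidate(d$X, d$y, classifierConfig(k), seed = 54)
    expect_gte(r@means[["accuracy"]], 0.95)
  }
})

test_that("Gaussian naive Bayes uses per-class sample moments", {
  set.seed(55)
  x0 <- rnorm(40, 2, 1.5); x1 <- rnorm(60, -1, 0.5)
  X <- matrix(c(x0, x1), ncol = 1)
  y <- rep(c(0L, 1L), c(40, 60))
  m <- trainClassifier(X, y, classifierConfig("naive_bayes"))
  expect_equal(m@fit$class0$mu, mean(x0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m@fit$class1$mu, mean(x1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m@fit$class0$sigma2, var(x0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m@fit$class0$prior, 0.4)
  # prediction equals the hand-computed posterior argmax
  probe <- c(-2, 0, 0.5, 3)
  post <- function(v, mom) log(mom$prior) +
    dnorm(v, mom$mu, sqrt(mom$sigma2), log = TRUE)
  manual <- as.integer(post(probe, m@fit$class1) > post(probe, m@fit$class0))
  expect_equal(predict(m, matrix(probe, ncol = 1)), manual)
})

test_that("naive Bayes matches the reference implementation", {
  set.seed(56)
  X <- rbind(matrix(rnorm(160, 1), 80, 2), matrix(rnorm(160, -1), 80, 2))
  y <- rep(c(1L, 0L), each = 80)
  ours <- trainClassifier(X, y, classifierConfig("naive_bayes"))
  ref <- e1071::naiveBayes(X, factor(y, levels = c(0, 1)))
  probe <- matrix(rnorm(60), 30, 2)
  refPred <- as.integer(as.character(predict(ref, probe)))
  expect_equal(predict(ours, probe), refPred)
})

test_that("gaussian likelihood matches the normal density formula", {
  expect_equal(gaussianLikelihood(0, 0, 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(gaussianLikelihood(1.7, 0.5, 2),
               gaussianLikelihood(-0.7, 0.5, 2))
  v <- 1.3; mu <- 0.2; s2 <- 0.7
  expect_equal(log(gaussianLikelihood(v, mu, s2)),
               -0.5 * log(2 * pi * s2) - (v - mu)^2 / (2 * s2))
  expect_error(gaussianLikelihood(0, 0, 0), "positive")
})

test_that("decision ties resolve to no-change", {
  # symmetric classes, probe exactly on the boundary
  X <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(0L, 0L, 1L, 1L)
  m <- trainClassifier(X, y, classifierConfig("naive_bayes"))
  expect_equal(predict(m, matrix(0, 1, 1)), 0L)
  # the label mapping round trip is lossless
  lab <- c(0L, 1L, 1L, 0L)
  pm <- ifelse(lab == 1L, 1L, -1L)
  expect_identical(as.integer(pm > 0), lab)
})

test_that("standardization makes margin models scale-invariant", {
  d <- separable2d(n = 80, gap = 3, seed = 57)
  probe <- matrix(rnorm(40), 20, 2)
  for (k in c("svm", "logistic")) {
    m1 <- trainClassifier(d$X, d$y, classifierConfig(k))
    m2 <- trainClassifier(d$X * 1000, d$y, classifierConfig(k))
    expect_equal(predict(m1, probe), predict(m2, probe * 1000), info = k)
  }
})

test_that("cross-validation uses 90/10 splits and is reproducible", {
  d <- separable2d(n = 160, gap = 3, seed = 58)
  r <- crossValidate(d$X, d$y, classifierConfig("naive_bayes"), seed = 59)
  expect_equal(nrow(r@folds), 10)
  expect_true(all(r@folds$nTrain == 144))
  expect_true(all(r@folds$nTest == 16))
  r2 <- crossValidate(d$X, d$y, classifierConfig("naive_bayes"), seed = 59)
  expect_identical(r@folds, r2@folds)
  r3 <- crossValidate(d$X, d$y, classifierConfig("naive_bayes"), seed = 60)
  expect_false(identical(r@folds$accuracy, r3@folds$accuracy))
  # metrics bounded, sd non-negative (class validity)
  expect_true(validObject(r))
  # table formatting mirrors the mean (+/- std) layout
  txt <- formatEvalTable(r)
  expect_match(txt[2], "naive_bayes")
  expect_match(txt[2], "\\(\\+/- ")
})
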