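#' Classifier configuration
#'
#' Settings for the five supported binary classifiers. `C` is the penalty
#' of the soft-margin linear SVM and of the L2-regularized logistic
#' regression (for the latter the ridge weight is `1/(n*C)` on glmnet's
#' per-observation scale, matching the unconstrained formulation
#' \eqn{\min_w \frac12 w^T w + C \sum_i \log(1 + e^{-y_i w^T x_i})}).
#' Features are standardized with training-fold mean/variance for the
#' margin-based models (SVM, logistic); trees, forests and naive Bayes see
#' raw features.
#'
#' @param kind one of `"svm"`, `"logistic"`, `"naive_bayes"`,
#'   `"decision_tree"`, `"random_forest"`.
#' @param C penalty parameter (> 0) for SVM / logistic regression.
#' @param treeCp complexity parameter of the decision tree (rpart `cp`).
#' @param treeMaxDepth maximum tree depth.
#' @param nTrees forest size.
#' @param standardize override the per-kind standardization default.
#' @param seed RNG seed for the stochastic backends.
#' @return list of class `ClassifierConfig`
#' @export
classifierConfig <- function(kind = c("svm", "logistic", "naive_bayes",
                                      "decision_tree", "random_forest"),
                             C = 1, treeCp = 1e-4, treeMaxDepth = 30L,
                             nTrees = 100L, standardize = NULL,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (C <= 0) stop("C must be positive")
  if (is.null(standardize)) standardize <- kind %in% c("svm", "logistic")
  structure(list(kind = kind, C = C, treeCp = treeCp,
                 treeMaxDepth = as.integer(treeMaxDepth),
                 nTrees = as.integer(nTrees), standardize = standardize,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' Gaussian likelihood of an observation
#'
#' The class-conditional likelihood used by Gaussian naive Bayes: the
#' normal density of `v` under mean `mu` and variance `sigma2`.
#'
#' @param v observed value(s)
#' @param mu class mean
#' @param sigma2 class variance (> 0)
#' @return density value(s)
#' @export
gaussianLikelihood <- function(v, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  dnorm(v, mean = mu, sd = sqrt(sigma2))
}

#' Train a binary behavior classifier
#'
#' Fits the configured backend on features and 0/1 labels (1 = behavioral
#' change). Gaussian naive Bayes is fitted in-package from per-class,
#' per-feature sample moments; the other kinds dispatch to the standard
#' implementations (e1071, glmnet, rpart, randomForest).
#'
#' @param features n x d numeric matrix
#' @param labels 0/1 vector of length n, both classes present
#' @param config a [classifierConfig()]
#' @return a [FishClassifier-class]
#' @export
trainClassifier <- function(features, labels,
                            config = classifierConfig()) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stop("one label per feature row required")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (!all(is.finite(X))) stop("features contain NaN/NA/Inf")
  colnames(X) <- NULL # prediction uses positional columns
  ctr <- numeric(0); scl <- numeric(0)
  if (config$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  fit <- withSeed(config$seed, switch(config$kind,
    svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                     cost = config$C, scale = FALSE),
    logistic = glmnet::glmnet(X, factor(y, levels = c(0, 1)),
                              family = "binomial", alpha = 0,
                              lambda = 1 / (config$C * nrow(X)),
                              standardize = FALSE, thresh = 1e-10),
    naive_bayes = {
      moments <- lapply(c(0L, 1L), function(k) {
        xs <- X[y == k, , drop = FALSE]
        v <- apply(xs, 2, var)
        v[!is.finite(v) | v < 1e-9] <- 1e-9
        list(prior = mean(y == k), mu = colMeans(xs), sigma2 = v)
      })
      names(moments) <- c("class0", "class1")
      moments
    },
    decision_tree = {
      df <- data.frame(y = factor(y, levels = c(0, 1)), X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = config$treeCp, maxdepth = config$treeMaxDepth,
                     xval = 0))
    },
    random_forest = randomForest::randomForest(
      X, factor(y, levels = c(0, 1)), ntree = config$nTrees)
  ))
  new("FishClassifier", kind = config$kind, fit = fit,
      config = unclass(config), center = ctr, scale = scl,
      featureDim = ncol(X))
}

# Signed score for class 1; prediction is 1 iff score > 0 (ties -> 0).
classifierScore <- function(object, X) {
  switch(object@kind,
    svm = {
      dv <- attr(predict(object@fit, X, decision.values = TRUE),
                 "decision.values")
      # e1071's decision value is positive for the class named first in the
      # column label ("0/1" vs "1/0" follows training-data order)
      pos <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      if (pos == "1") as.numeric(dv) else -as.numeric(dv)
    },
    logistic = as.numeric(predict(object@fit, newx = X, type = "link")),
    naive_bayes = {
      lp <- vapply(object@fit, function(m) {
        lg <- dnorm(X, mean = rep(m$mu, each = nrow(X)),
                    sd = rep(sqrt(m$sigma2), each = nrow(X)), log = TRUE)
        rowSums(matrix(lg, nrow(X))) + log(m$prior)
      }, numeric(nrow(X)))
      lp <- matrix(lp, nrow = nrow(X))
      lp[, 2] - lp[, 1]
    },
    decision_tree = {
      p <- predict(object@fit, newdata = data.frame(X), type = "prob")
      p[, "1"] - p[, "0"]
    },
    random_forest = {
      p <- predict(object@fit, X, type = "prob")
      p[, "1"] - p[, "0"]
    })
}

#' Predict behavioral-change labels
#'
#' Hard 0/1 labels for new feature vectors; a tied decision score resolves
#' conservatively to 0 ("no change").
#'
#' @param object a [FishClassifier-class]
#' @param newdata length-d vector or m x d matrix
#' @return integer vector of 0/1 labels
#' @export
setMethod("predict", "FishClassifier", function(object, newdata) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(X) != object@featureDim)
    stop(sprintf("feature dimension %d does not match training (%d)",
                 ncol(X), object@featureDim))
  if (length(object@center))
    X <- sweep(sweep(X, 2, object@center), 2, object@scale, "/")
  colnames(X) <- NULL
  as.integer(classifierScore(object, X) > 0)
})

#' Binary classification metrics
#'
#' Positive class is 1 (behavioral change). Precision = TP/(TP+FP), recall
#' = TP/(TP+FN), F1 = harmonic mean of the two; empty denominators yield 0
#' by convention.
#'
#' @param yTrue,yPred equal-length 0/1 vectors
#' @return named numeric: `accuracy`, `precision`, `recall`, `f1`
#' @examples
#' evaluateMetrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
evaluateMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (!all(c(yTrue, yPred) %in% c(0, 1))) stop("labels must be 0/1")
  tp <- sum(yTrue == 1 & yPred == 1)
  fp <- sum(yTrue == 0 & yPred == 1)
  fn <- sum(yTrue == 1 & yPred == 0)
  tn <- sum(yTrue == 0 & yPred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = (tp + tn) / length(yTrue), precision = prec, recall = rec,
    f1 = f1)
}

#' Repeated random-subsampling cross-validation
#'
#' The evaluation protocol for the behavior classifiers: `nFolds`
#' independent random splits, each holding out `round(n * testFraction)`
#' items (stratified by class by default) and training on the remaining
#' 90%. With 160 items this gives 144 train / 16 test per fold; with the
#' 20,000-vector augmented set, 18,000 / 2,000. Reports per-fold accuracy,
#' precision, recall and F1 plus their means and standard deviations.
#'
#' @param features n x d matrix
#' @param labels 0/1 vector
#' @param config a [classifierConfig()]
#' @param nFolds number of random splits (default 10)
#' @param testFraction held-out fraction per split (default 0.1)
#' @param stratified sample the test set per class (default TRUE)
#' @param seed seed controlling all splits (fixed seed = identical report)
#' @return an [EvalReport-class]
#' @export
crossValidate <- function(features, labels, config = classifierConfig(),
                          nFolds = 10, testFraction = 0.1,
                          stratified = TRUE, seed = 1L) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  n <- nrow(X)
  nTest <- round(n * testFraction)
  if (nTest < 1 || nTest >= n) stop("testFraction leaves an empty split")
  rows <- withSeed(seed, {
    lapply(seq_len(nFolds), function(f) {
      for (attempt in seq_len(100)) {
        test <- if (stratified) {
          idx0 <- which(y == 0L); idx1 <- which(y == 1L)
          n1 <- round(nTest * length(idx1) / n)
          c(sample(idx1, n1), sample(idx0, nTest - n1))
        } else sample(n, nTest)
        train <- setdiff(seq_len(n), test)
        if (length(unique(y[train])) == 2 && length(test) > 0) break
        if (attempt == 100) stop("could not draw a split with both classes")
        warning("resampling a split whose training part lost a class")
      }
      cfg <- config
      cfg$seed <- deriveSeed(config$seed, f)
      fit <- trainClassifier(X[train, , drop = FALSE], y[train], cfg)
      pred <- predict(fit, X[test, , drop = FALSE])
      c(fold = f, evaluateMetrics(y[test], pred),
        nTrain = length(train), nTest = length(test))
    })
  })
  folds <- as.data.frame(do.call(rbind, rows))
  mets <- c("accuracy", "precision", "recall", "f1")
  new("EvalReport", folds = folds,
      means = vapply(mets, function(m) mean(folds[[m]]), numeric(1)),
      sds = vapply(mets, function(m) sd(folds[[m]]), numeric(1)),
      kind = config$kind)
}

#' Format an evaluation report as a plain-text table
#'
#' One row per classifier, `mean (+/- std)` per metric, mirroring the
#' layout used in classification-evaluation tables.
#'
#' @param reports a single [EvalReport-class] or a list of them
#' @return character vector of table lines
#' @export
formatEvalTable <- function(reports) {
  if (is(reports, "EvalReport")) reports <- list(reports)
  mets <- c("accuracy", "precision", "recall", "f1")
  header <- sprintf("%-15s %-18s %-18s %-18s %-18s", "Classifier",
                    "Accuracy", "Precision", "Recall", "F1")
  lines <- vapply(reports, function(r) {
    cells <- vapply(mets, function(m)
      sprintf("%.3f (+/- %.3f)", r@means[[m]], r@sds[[m]]), character(1))
    sprintf("%-15s %-18s %-18s %-18s %-18s", r@kind, cells[1], cells[2],
            cells[3], cells[4])
  }, character(1))
  c(header, lines)
}
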