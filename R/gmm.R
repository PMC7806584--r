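#' Fit a Gaussian mixture model by expectation maximization
#'
#' Models a feature cloud as \eqn{p(x) = \sum_{i=1}^K \phi_i
#' N(x | \mu_i, \sigma_i)} with \eqn{\sum_i \phi_i = 1}. Responsibilities
#' are computed in log space (log-sum-exp); means/variances come from a
#' k-means start. The per-iteration log-likelihood trace is stored and is
#' non-decreasing up to numerical tolerance. Covariances are diagonal by
#' default (suited to few samples in 64 dimensions) with a small ridge
#' (`reg`) added for numerical stability; near-singular components are
#' regularized with a warning.
#'
#' @param features n x d matrix (or length-n vector for d = 1)
#' @param K number of mixture components (default 2)
#' @param covType `"diagonal"` or `"full"`
#' @param seed RNG seed for the k-means initialization
#' @param maxIter,tol EM stopping rule (relative log-likelihood change)
#' @param reg diagonal ridge added to every covariance
#' @param classLabel optional 0/1 class annotation carried in the result
#' @return a [GMMParams-class]
#' @examples
#' x <- c(rnorm(100, -3), rnorm(100, 3))
#' fitGMM(x, K = 2, seed = 1)
#' @export
fitGMM <- function(features, K = 2, covType = c("diagonal", "full"),
                   seed = 1L, maxIter = 200, tol = 1e-8, reg = 1e-6,
                   classLabel = NA_integer_) {
  covType <- match.arg(covType)
  X <- if (is.null(dim(features))) matrix(features, ncol = 1) else
    as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop(sprintf("K = %d exceeds the %d available samples", K, n))
  if (!all(is.finite(X))) stop("features must be finite")

  withSeed(seed, {
    if (K == 1) {
      assign0 <- rep(1L, n)
    } else {
      assign0 <- tryCatch(
        suppressWarnings(kmeans(X, centers = K, nstart = 5,
                                iter.max = 50)$cluster),
        error = function(e) sample.int(K, n, replace = TRUE))
    }
    w <- as.numeric(tabulate(assign0, K)) / n
    mu <- matrix(unlist(lapply(seq_len(K), function(k) {
      if (any(assign0 == k)) colMeans(X[assign0 == k, , drop = FALSE])
      else X[sample(n, 1), ]
    })), nrow = K, byrow = TRUE)
    lowVar <- FALSE
    if (covType == "diagonal") {
      sg <- matrix(unlist(lapply(seq_len(K), function(k) {
        xs <- X[assign0 == k, , drop = FALSE]
        v <- if (nrow(xs) > 1) apply(xs, 2, var) * (nrow(xs) - 1) / nrow(xs)
        else numeric(d)
        v + reg
      })), nrow = K, byrow = TRUE)
      covs <- list()
    } else {
      covs <- lapply(seq_len(K), function(k) {
        xs <- X[assign0 == k, , drop = FALSE]
        v <- if (nrow(xs) > 1) cov(xs) * (nrow(xs) - 1) / nrow(xs)
        else matrix(0, d, d)
        v + diag(reg, d)
      })
      sg <- matrix(0, K, d)
    }

    logCompDens <- function() {
      # n x K matrix of log N(x | mu_k, sigma_k)
      out <- matrix(0, n, K)
      for (k in seq_len(K)) {
        if (covType == "diagonal") {
          v <- sg[k, ]
          q <- sweep(sweep(X, 2, mu[k, ])^2, 2, v, "/")
          out[, k] <- -0.5 * (d * log(2 * pi) + sum(log(v)) + rowSums(q))
        } else {
          ch <- chol(covs[[k]])
          xc <- sweep(X, 2, mu[k, ])
          z <- xc %*% backsolve(ch, diag(d))
          out[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                                rowSums(z * z))
        }
      }
      out
    }

    llTrace <- numeric(0)
    for (it in seq_len(maxIter)) {
      lg <- sweep(logCompDens(), 2, log(pmax(w, 1e-300)), "+")
      mx <- apply(lg, 1, max)
      lse <- mx + log(rowSums(exp(lg - mx)))
      ll <- sum(lse)
      llTrace <- c(llTrace, ll)
      resp <- exp(lg - lse)
      Nk <- colSums(resp)
      w <- Nk / n
      mu <- sweep(crossprod(resp, X), 1, pmax(Nk, 1e-300), "/")
      if (covType == "diagonal") {
        sg2 <- sweep(crossprod(resp, X^2), 1, pmax(Nk, 1e-300), "/") - mu^2
        if (any(sg2 < 1e-10)) lowVar <- TRUE
        sg <- pmax(sg2, 0) + reg
      } else {
        for (k in seq_len(K)) {
          xc <- sweep(X, 2, mu[k, ])
          Ck <- crossprod(xc * resp[, k], xc) / max(Nk[k], 1e-300)
          if (min(eigen(Ck, symmetric = TRUE, only.values = TRUE)$values) <
              1e-10) lowVar <- TRUE
          covs[[k]] <- Ck + diag(reg, d)
        }
      }
      if (it > 1 && abs(ll - llTrace[it - 1]) <=
            tol * (abs(ll) + .Machine$double.eps)) break
    }
    if (lowVar)
      warning("near-singular covariance regularized (ridge on the diagonal)")
    new("GMMParams", weights = w, means = mu, variances = sg,
        covariances = covs, covType = covType, logLik = llTrace,
        classLabel = as.integer(classLabel), seed = as.integer(seed))
  })
}

#' Mixture density at one or more points
#'
#' Evaluates \eqn{p(x) = \sum_i \phi_i N(x | \mu_i, \sigma_i)}.
#'
#' @param params a [GMMParams-class]
#' @param x length-d vector or m x d matrix
#' @return numeric density value(s), >= 0
#' @export
gmmDensity <- function(params, x) {
  d <- ncol(params@means)
  X <- if (is.null(dim(x))) {
    if (d == 1) matrix(x, ncol = 1) else matrix(x, nrow = 1)
  } else as.matrix(x)
  if (ncol(X) != d)
    stop(sprintf("x has dimension %d; the mixture has %d", ncol(X), d))
  K <- length(params@weights)
  lg <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    if (params@covType == "diagonal") {
      v <- params@variances[k, ]
      q <- sweep(sweep(X, 2, params@means[k, ])^2, 2, v, "/")
      lg[, k] <- -0.5 * (d * log(2 * pi) + sum(log(v)) + rowSums(q))
    } else {
      ch <- chol(params@covariances[[k]])
      xc <- sweep(X, 2, params@means[k, ])
      z <- xc %*% backsolve(ch, diag(d))
      lg[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                           rowSums(z * z))
    }
    lg[, k] <- lg[, k] + log(pmax(params@weights[k], 1e-300))
  }
  mx <- apply(lg, 1, max)
  as.numeric(exp(mx + log(rowSums(exp(lg - mx)))))
}

#' Sample synthetic feature vectors from a fitted mixture
#'
#' Each draw picks a component with probabilities \eqn{\phi} and then draws
#' from that component's normal distribution — the generative sampling that
#' enlarges the training set (the working default is 10,000 vectors per
#' class).
#'
#' @param params a [GMMParams-class]
#' @param n number of samples (>= 1)
#' @param seed RNG seed
#' @return n x d matrix with attribute `components` (the component index of
#'   each draw)
#' @export
sampleGMM <- function(params, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  K <- length(params@weights)
  d <- ncol(params@means)
  withSeed(seed, {
    comp <- sample.int(K, n, replace = TRUE, prob = params@weights)
    if (params@covType == "diagonal") {
      Z <- matrix(rnorm(n * d), n, d)
      out <- params@means[comp, , drop = FALSE] +
        Z * sqrt(params@variances[comp, , drop = FALSE])
    } else {
      out <- matrix(0, n, d)
      for (k in seq_len(K)) {
        idx <- which(comp == k)
        if (!length(idx)) next
        ch <- chol(params@covariances[[k]])
        out[idx, ] <- matrix(rnorm(length(idx) * d), length(idx)) %*% ch +
          rep(params@means[k, ], each = length(idx))
      }
    }
    attr(out, "components") <- comp
    out
  })
}

#' Augment a labeled feature set by class-conditional GMM sampling
#'
#' Fits one mixture per behavior class on the training features only, then
#' samples `nPerClass` synthetic vectors from each, labeled with the class
#' of the generating mixture. Following the augmented-evaluation protocol,
#' the returned set contains the synthetic vectors only; `includeReal =
#' TRUE` appends the real features (a provenance column tells them apart).
#'
#' @param features n x d matrix of (real) feature vectors
#' @param labels 0/1 vector, both classes present
#' @param nPerClass synthetic samples per class (default 10000)
#' @param K components per class mixture (default 2)
#' @param covType covariance structure, see [fitGMM()]
#' @param seed master seed (per-class fitting/sampling seeds derive from it)
#' @param includeReal also return the real features
#' @return list with `features`, `labels`, `provenance`
#'   ("synthetic"/"real"), and the fitted mixtures `gmmNeg`, `gmmPos`
#' @export
augmentDataset <- function(features, labels, nPerClass = 10000L, K = 2,
                           covType = c("diagonal", "full"), seed = 1L,
                           includeReal = FALSE) {
  covType <- match.arg(covType)
  X <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both behavior classes must be present in the training data")
  g0 <- fitGMM(X[labels == 0L, , drop = FALSE], K = K, covType = covType,
               seed = deriveSeed(seed, 1), classLabel = 0L)
  g1 <- fitGMM(X[labels == 1L, , drop = FALSE], K = K, covType = covType,
               seed = deriveSeed(seed, 2), classLabel = 1L)
  s0 <- sampleGMM(g0, nPerClass, seed = deriveSeed(seed, 3))
  s1 <- sampleGMM(g1, nPerClass, seed = deriveSeed(seed, 4))
  feat <- rbind(s0, s1)
  lab <- c(rep(0L, nPerClass), rep(1L, nPerClass))
  prov <- rep("synthetic", 2 * nPerClass)
  if (includeReal) {
    feat <- rbind(feat, X)
    lab <- c(lab, labels)
    prov <- c(prov, rep("real", nrow(X)))
  }
  attr(feat, "components") <- NULL
  list(features = feat, labels = lab, provenance = prov,
       gmmNeg = g0, gmmPos = g1)
}
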