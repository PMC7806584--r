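#' Autoencoder configuration
#'
#' Settings for the trajectory-image autoencoder: a single-hidden-layer
#' model with encoder \eqn{y = s(Wx + b)} and decoder \eqn{z = s(W'y + b')}
#' over flattened images \eqn{x \in [0,1]^d}. The latent dimension defaults
#' to 64, balancing feature dimensionality against corpus size; the sweep
#' set {16, 32, 64, 128} is what the reconstruction-monotonicity diagnostics
#' use.
#'
#' Initialization `"pca"` (default) starts the model at a linearized
#' principal-component solution (encoder along the top latent-dim principal
#' axes, decoder at the matching first-order inverse of the output
#' nonlinearity), which makes short trainings converge reliably and makes
#' capacity strictly nested across latent dimensions; `"random"` is a
#' scaled Gaussian (Glorot) start, also used as the untrained baseline.
#'
#' @param latentDim size of the latent code d' (must be < d at training).
#' @param nonlinearity `"sigmoid"` or `"relu"` (cross-entropy loss always
#'   uses a sigmoid output layer).
#' @param loss `"squared_error"` or `"cross_entropy"`.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param init `"pca"` or `"random"`.
#' @param seed RNG seed: identical config + data give identical models.
#' @return list of class `AutoencoderConfig`
#' @export
autoencoderConfig <- function(latentDim = 64L,
                              nonlinearity = c("sigmoid", "relu"),
                              loss = c("squared_error", "cross_entropy"),
                              epochs = 12L, batchSize = 32L,
                              learningRate = 1e-3,
                              init = c("pca", "random"), seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  loss <- match.arg(loss)
  init <- match.arg(init)
  stopifnot(latentDim >= 1, epochs >= 0, batchSize >= 1, learningRate > 0)
  structure(list(latentDim = as.integer(latentDim),
                 nonlinearity = nonlinearity, loss = loss,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, init = init,
                 seed = as.integer(seed)),
            class = "AutoencoderConfig")
}

applyNonlin <- function(u, kind) {
  if (kind == "sigmoid") sigmoid(u) else pmax(u, 0)
}

# images: list of equal-shape arrays, or an n x d matrix (rows = images).
imagesToMatrix <- function(images) {
  if (is.matrix(images)) {
    attr(images, "inputDim") <- c(ncol(images), 1L, 1L)
    return(images)
  }
  stopifnot(is.list(images), length(images) >= 1)
  d0 <- dim(images[[1]])
  if (is.null(d0)) d0 <- length(images[[1]])
  X <- t(vapply(images, function(im) as.numeric(im),
                numeric(prod(d0))))
  attr(X, "inputDim") <- as.integer(c(d0, rep(1L, 3 - length(d0))))
  X
}

#' Train the trajectory-image autoencoder
#'
#' Minimizes the reconstruction loss with Adam over minibatches. The
#' returned model records the per-epoch training loss; with the default PCA
#' initialization the final-epoch loss does not exceed the first-epoch
#' loss, and larger latent dimensions reconstruct at most as badly as
#' smaller ones on the same data.
#'
#' @param images list of (h, w, c) arrays with values in [0, 1] (>= 2), or
#'   an n x d matrix of flattened images
#' @param config an [autoencoderConfig()]
#' @return a trained [Autoencoder-class]
#' @export
trainAutoencoder <- function(images, config = autoencoderConfig()) {
  X <- imagesToMatrix(images)
  inputDim <- attr(X, "inputDim")
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 images")
  rng <- range(X)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("pixel values must be normalized to [0, 1]")
  dL <- config$latentDim
  if (dL >= d)
    stop("latent dimension must be smaller than the input dimension")
  s <- config$nonlinearity
  sOut <- if (config$loss == "cross_entropy") "sigmoid" else s

  withSeed(config$seed, {
    m <- colMeans(X)
    if (config$init == "pca") {
      Xc <- X - rep(m, each = n)
      S <- tcrossprod(Xc)
      eg <- eigen(S, symmetric = TRUE)
      pos <- which(eg$values > max(eg$values) * 1e-10)
      ncomp <- min(dL, length(pos))
      lam <- eg$values[seq_len(ncomp)]
      V <- crossprod(Xc, eg$vectors[, seq_len(ncomp), drop = FALSE])
      V <- sweep(V, 2, sqrt(lam), "/")          # orthonormal axes, d x ncomp
      sdev <- sqrt(lam / n)                     # score std per axis
      W <- matrix(rnorm(d * dL, sd = 1e-3), d, dL)
      b <- numeric(dL)
      W[, seq_len(ncomp)] <- sweep(V, 2, 2 * sdev, "/")
      b[seq_len(ncomp)] <- -as.numeric(m %*% V) / (2 * sdev)
      # decoder: principal axes scaled to the latent units' linear range,
      # output bias at the logit of the (clamped) pixel means; no slope
      # amplification -- large initial weights saturate the output sigmoid
      # and stall training
      mt <- pmin(pmax(m, 0.05), 0.95)
      Wp <- matrix(0, dL, d)
      Wp[seq_len(ncomp), ] <- t(sweep(V, 2, 8 * sdev, "*"))
      bp <- logit(mt) - 0.5 * colSums(Wp)
      rm(Xc, S, eg, V)
    } else {
      W <- matrix(rnorm(d * dL, sd = sqrt(2 / (d + dL))), d, dL)
      b <- numeric(dL)
      Wp <- matrix(rnorm(dL * d, sd = sqrt(2 / (d + dL))), dL, d)
      bp <- numeric(d)
    }

    lossHistory <- numeric(0)
    if (config$epochs > 0) {
      lr <- config$learningRate
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      mW <- W * 0; vW <- W * 0; mWp <- Wp * 0; vWp <- Wp * 0
      mb <- b * 0; vb <- b * 0; mbp <- bp * 0; vbp <- bp * 0
      step <- 0
      for (ep in seq_len(config$epochs)) {
        perm <- sample(n)
        starts <- seq(1, n, by = config$batchSize)
        epLoss <- 0; epN <- 0
        for (st in starts) {
          idx <- perm[st:min(st + config$batchSize - 1, n)]
          nb <- length(idx)
          Xb <- X[idx, , drop = FALSE]
          U1 <- Xb %*% W + rep(b, each = nb)
          H <- applyNonlin(U1, s)
          U2 <- H %*% Wp + rep(bp, each = nb)
          Z <- applyNonlin(U2, sOut)
          if (config$loss == "squared_error") {
            R <- Z - Xb
            loss <- mean(R * R)
            dU2 <- 2 * R / (nb * d)
            if (sOut == "sigmoid") dU2 <- dU2 * Z * (1 - Z)
            else dU2 <- dU2 * (U2 > 0)
          } else {
            Zc <- pmin(pmax(Z, 1e-12), 1 - 1e-12)
            loss <- -mean(Xb * log(Zc) + (1 - Xb) * log(1 - Zc))
            dU2 <- (Z - Xb) / (nb * d)
          }
          dWp <- crossprod(H, dU2)
          dbp <- colSums(dU2)
          dH <- tcrossprod(dU2, Wp)
          rm(dU2, Z, U2)
          dU1 <- if (s == "sigmoid") dH * H * (1 - H) else dH * (U1 > 0)
          rm(dH, H, U1)
          dW <- crossprod(Xb, dU1)
          db <- colSums(dU1)
          rm(dU1, Xb)
          step <- step + 1
          c1 <- 1 - b1^step; c2 <- 1 - b2^step
          # in-place updates: the weight matrices are large enough that
          # R-level temporaries would dominate the training time
          cppAdamStep(W, mW, vW, dW, lr, b1, b2, c1, c2, eps)
          cppAdamStep(Wp, mWp, vWp, dWp, lr, b1, b2, c1, c2, eps)
          cppAdamStep(b, mb, vb, db, lr, b1, b2, c1, c2, eps)
          cppAdamStep(bp, mbp, vbp, dbp, lr, b1, b2, c1, c2, eps)
          epLoss <- epLoss + loss * nb
          epN <- epN + nb
        }
        lossHistory <- c(lossHistory, epLoss / epN)
      }
    }
    new("Autoencoder", W = W, b = b, Wp = Wp, bp = bp,
        config = unclass(config), inputDim = inputDim,
        lossHistory = lossHistory, trained = config$epochs > 0)
  })
}

#' Encode trajectory images to feature vectors
#'
#' @param model a trained [Autoencoder-class]
#' @param images one (h, w, c) array, a list of them, or an n x d matrix
#' @return a numeric vector of length `latentDim(model)` for one image, or
#'   an n x latentDim matrix
#' @export
encodeTrajectory <- function(model, images) {
  single <- !is.list(images) && !is.matrix(images)
  if (single) images <- list(images)
  X <- imagesToMatrix(images)
  if (ncol(X) != nrow(model@W))
    stop(sprintf("image has %d values; the model expects %d", ncol(X),
                 nrow(model@W)))
  Y <- applyNonlin(X %*% model@W + rep(model@b, each = nrow(X)),
                   model@config$nonlinearity)
  if (single) as.numeric(Y) else Y
}

#' Decode feature vectors back to images
#'
#' @param model a trained [Autoencoder-class]
#' @param codes numeric vector of length latentDim, or an n x latentDim
#'   matrix
#' @return one reconstructed image array (or a list for a matrix of codes)
#'   with the training input shape
#' @export
decodeTrajectory <- function(model, codes) {
  single <- is.null(dim(codes))
  if (single) codes <- matrix(codes, nrow = 1)
  if (ncol(codes) != ncol(model@W))
    stop(sprintf("code has %d values; the model expects %d", ncol(codes),
                 ncol(model@W)))
  sOut <- if (model@config$loss == "cross_entropy") "sigmoid"
          else model@config$nonlinearity
  Z <- applyNonlin(codes %*% model@Wp + rep(model@bp, each = nrow(codes)),
                   sOut)
  flat <- all(model@inputDim[-1] == 1L)
  toImg <- function(z) if (flat) as.numeric(z) else
    array(z, dim = model@inputDim)
  if (single) toImg(Z[1, ]) else lapply(seq_len(nrow(Z)), function(i)
    toImg(Z[i, ]))
}

#' Reconstruction error between an image and its reconstruction
#'
#' Squared error is the mean of (x - z)^2 over all values; cross-entropy is
#' the mean per-value Bernoulli cross-entropy (images read as vectors of
#' bit probabilities).
#'
#' @param x,z arrays/vectors of identical shape
#' @param loss `"squared_error"` or `"cross_entropy"`
#' @return scalar >= 0
#' @export
reconstructionError <- function(x, z,
                                loss = c("squared_error", "cross_entropy")) {
  loss <- match.arg(loss)
  if (!isTRUE(all.equal(dim(x), dim(z))) || length(x) != length(z))
    stop("x and z must have identical shapes")
  if (loss == "squared_error") return(mean((x - z)^2))
  zc <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  -mean(x * log(zc) + (1 - x) * log(1 - zc))
}
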