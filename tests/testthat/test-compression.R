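# Small random image batches train in well under a second, so most
# contracts are exercised at reduced input size; full 256x256x3 behavior is
# covered by the acceptance suite.

smallImages <- function(n, side = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(runif(side * side * 3),
                                       c(side, side, 3)))
}

test_that("training validates its inputs", {
  imgs <- smallImages(6)
  expect_error(trainAutoencoder(imgs[1], autoencoderConfig(latentDim = 4)),
               "at least 2")
  bad <- imgs; bad[[2]][1] <- 2
  expect_error(trainAutoencoder(bad, autoencoderConfig(latentDim = 4)),
               "normalized")
  expect_error(trainAutoencoder(imgs,
                                autoencoderConfig(latentDim = 8 * 8 * 3)),
               "smaller")
})

test_that("training reduces the loss and is seed-deterministic", {
  imgs <- smallImages(24)
  cfg <- autoencoderConfig(latentDim = 6, epochs = 25, batchSize = 8,
                           seed = 3)
  ae <- trainAutoencoder(imgs, cfg)
  expect_length(ae@lossHistory, 25)
  expect_lte(ae@lossHistory[25], ae@lossHistory[1])
  ae2 <- trainAutoencoder(imgs, cfg)
  expect_identical(ae@W, ae2@W)
  expect_identical(ae@lossHistory, ae2@lossHistory)
  # a different seed gives a different trajectory
  cfg2 <- cfg; cfg2$seed <- 4L
  ae3 <- trainAutoencoder(imgs, cfg2)
  expect_false(identical(ae@lossHistory, ae3@lossHistory))
})

test_that("encode/decode respect shapes, codomain and determinism", {
  imgs <- smallImages(16, seed = 5)
  ae <- trainAutoencoder(imgs, autoencoderConfig(latentDim = 5, epochs = 10,
                                                 batchSize = 8))
  code <- encodeTrajectory(ae, imgs[[1]])
  expect_length(code, 5)
  expect_true(all(is.finite(code)))
  expect_true(all(code >= 0 & code <= 1)) # sigmoid codomain
  expect_identical(code, encodeTrajectory(ae, imgs[[1]]))
  z <- decodeTrajectory(ae, code)
  expect_equal(dim(z), dim(imgs[[1]]))
  expect_true(all(z >= 0 & z <= 1))
  # batch interface agrees with single-image calls
  Y <- encodeTrajectory(ae, imgs[1:3])
  expect_equal(dim(Y), c(3, 5))
  expect_equal(as.numeric(Y[1, ]), code)
  expect_error(encodeTrajectory(ae, array(0.1, c(4, 4, 3))), "expects")
  expect_error(decodeTrajectory(ae, rep(0.5, 7)), "expects")
})

test_that("a trained model beats its untrained initialization", {
  # images drawn from a 3-dimensional family, so learning generalizes
  basis <- smallImages(3, seed = 6)
  lowRank <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      w <- runif(3)
      clamp <- function(x) pmin(pmax(x, 0), 1)
      clamp(w[1] * basis[[1]] + w[2] * basis[[2]] + w[3] * basis[[3]])
    })
  }
  imgs <- lowRank(30, seed = 7)
  hold <- lowRank(10, seed = 8)
  cfgT <- autoencoderConfig(latentDim = 6, epochs = 40, batchSize = 8,
                            init = "random", seed = 2)
  cfg0 <- cfgT; cfg0$epochs <- 0L
  trained <- trainAutoencoder(imgs, cfgT)
  untrained <- trainAutoencoder(imgs, cfg0)
  err <- function(m) mean(vapply(hold, function(x)
    reconstructionError(x, decodeTrajectory(m, encodeTrajectory(m, x))),
    numeric(1)))
  expect_lt(err(trained), err(untrained))
  expect_false(untrained@trained)
})

test_that("more latent dimensions reconstruct at least as well", {
  imgs <- smallImages(40, side = 8, seed = 9)
  errs <- vapply(c(4, 8, 16), function(dL) {
    ae <- trainAutoencoder(imgs, autoencoderConfig(latentDim = dL,
                                                   epochs = 15,
                                                   batchSize = 16, seed = 6))
    mean(vapply(imgs, function(x)
      reconstructionError(x, decodeTrajectory(ae, encodeTrajectory(ae, x))),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("the relu variant trains without leaving the finite range", {
  imgs <- smallImages(12, seed = 10)
  ae <- trainAutoencoder(imgs, autoencoderConfig(latentDim = 4, epochs = 10,
                                                 nonlinearity = "relu",
                                                 batchSize = 6,
                                                 init = "random"))
  code <- encodeTrajectory(ae, imgs[[1]])
  expect_true(all(is.finite(code)))
  expect_true(all(code >= 0)) # relu codomain is [0, Inf)
})

test_that("cross-entropy training decreases its own loss", {
  imgs <- smallImages(16, seed = 11)
  ae <- trainAutoencoder(imgs, autoencoderConfig(latentDim = 4, epochs = 20,
                                                 loss = "cross_entropy",
                                                 batchSize = 8))
  expect_lte(ae@lossHistory[20], ae@lossHistory[1])
})

test_that("latent codes separate opposite swim directions", {
  # four similar orbits per direction: on average, codes of
  # opposite-direction clips sit farther apart than codes of
  # same-direction clips (individual pairs vary, since the encoder
  # whitens components and can saturate on tiny batches)
  dirs <- rep(c("counterclockwise", "clockwise"), each = 4)
  angs <- rep(c(1.0, 1.15, 1.3, 1.45), 2)
  trajs <- lapply(1:8, function(i) {
    cfg <- tinyScene(duration = 1.5, fps = 8, swimDirection = dirs[i],
                     startAngle = angs[i], seed = 500 + i)
    o <- generateClip(cfg)
    clipToTrajectory(o$clip, detectClip(o$clip))
  })
  ae <- trainAutoencoder(trajs, autoencoderConfig(latentDim = 6,
                                                  epochs = 5,
                                                  batchSize = 8, seed = 2))
  codes <- encodeTrajectory(ae, trajs)
  d <- as.matrix(dist(codes))
  same <- c(d[1:4, 1:4][upper.tri(diag(4))],
            d[5:8, 5:8][upper.tri(diag(4))])
  cross <- as.vector(d[1:4, 5:8])
  expect_gt(mean(cross), mean(same))
})

test_that("reconstruction error matches closed forms", {
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(reconstructionError(x, x), 0)
  # all-0.5 cross-entropy is ln 2 per value
  h <- array(0.5, c(4, 4, 3))
  expect_equal(reconstructionError(h, h, "cross_entropy"), log(2))
  # squared error is symmetric
  y <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(reconstructionError(x, y), reconstructionError(y, x))
  expect_equal(reconstructionError(x, y), mean((x - y)^2))
  expect_error(reconstructionError(x, array(0.2, c(2, 2, 3))), "shape")
})
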