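test_that("masking keeps the disk and zeroes the rest", {
  fr <- matrix(runif(64 * 64), 64, 64)
  full <- matrix(TRUE, 64, 64)
  expect_identical(applyMask(fr, full), fr * 1)
  empty <- matrix(FALSE, 64, 64)
  expect_true(all(applyMask(fr, empty) == 0))
  m <- buildMask(c(64, 64), data.frame(x_min = 20, y_min = 20,
                                       x_max = 40, y_max = 40))
  masked <- applyMask(fr, m)
  expect_lte(sum(masked > 0), diskPixelCount(64, 64, 30, 30, 10))
  expect_error(applyMask(fr, matrix(TRUE, 32, 32)), "shape")
})

test_that("dense flow is near zero for identical frames and recovers a translation", {
  set.seed(7)
  a <- matrix(runif(128 * 128), 128, 128)
  f0 <- denseFlow(a, a)
  expect_lt(median(sqrt(f0$dx^2 + f0$dy^2)), 0.1)
  # textured blob moved +3 px along x
  img <- matrix(0, 128, 128)
  blob <- matrix(runif(31 * 31, 0.3, 1), 31, 31)
  img[50:80, 40:70] <- blob
  img2 <- matrix(0, 128, 128)
  img2[50:80, 43:73] <- blob
  fl <- denseFlow(img, img2)
  sel <- img > 0
  expect_lt(abs(median(fl$dx[sel]) - 3), 0.5)
  expect_lt(abs(median(fl$dy[sel]) - 0), 0.5)
  # and -2 px along y
  img3 <- matrix(0, 128, 128)
  img3[48:78, 40:70] <- blob
  fl2 <- denseFlow(img, img3)
  expect_lt(abs(median(fl2$dy[sel]) + 2), 0.5)
  expect_error(denseFlow(img, matrix(0, 64, 64)), "shape")
})

test_that("t frames yield exactly t-1 flow fields", {
  for (t in c(2, 5, 9)) {
    frames <- lapply(seq_len(t), function(k) {
      m <- matrix(0, 48, 48)
      m[20:28, (10 + k):(18 + k)] <- 0.9
      m
    })
    flows <- lapply(seq_len(t - 1), function(k)
      denseFlow(frames[[k]], frames[[k + 1]]))
    expect_length(flows, t - 1)
  }
})

test_that("flow images encode angle as hue and magnitude as value", {
  z <- list(dx = matrix(0, 8, 8), dy = matrix(0, 8, 8))
  expect_true(all(flowToImage(z) == 0))
  right <- flowToImage(list(dx = matrix(1, 8, 8), dy = matrix(0, 8, 8)))
  up <- flowToImage(list(dx = matrix(0, 8, 8), dy = matrix(1, 8, 8)))
  # uniform fields give uniform colors
  expect_equal(length(unique(as.vector(right[, , 1]))), 1)
  expect_false(isTRUE(all.equal(right, up)))
  # below the cap, doubling the magnitude doubles the value channel
  v1 <- flowToImage(list(dx = matrix(2, 4, 4), dy = matrix(0, 4, 4)))
  v2 <- flowToImage(list(dx = matrix(4, 4, 4), dy = matrix(0, 4, 4)))
  val <- function(img) max(img)
  expect_equal(val(v2), 2 * val(v1), tolerance = 1e-12)
})

test_that("fusion is a per-pixel max with fixed output shape", {
  set.seed(3)
  imgs <- lapply(1:5, function(i) array(runif(256 * 256 * 3),
                                        c(256, 256, 3)))
  fused <- fuseTrajectory(imgs)
  expect_equal(dim(fused), c(256, 256, 3))
  expect_equal(fused, Reduce(pmax, imgs))
  # identity on a single image
  expect_equal(fuseTrajectory(imgs[1]), imgs[[1]])
  # permutation invariance
  expect_equal(fuseTrajectory(imgs[c(4, 1, 5, 3, 2)]), fused)
  # resize path keeps the contract for other frame sizes
  small <- lapply(1:3, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(fuseTrajectory(small)), c(256, 256, 3))
  expect_error(fuseTrajectory(list()), "at least one")
})

test_that("a static clip fuses to a near-black trajectory image", {
  fr <- matrix(0, 96, 96)
  fr <- FishFlow:::paintEllipse(fr, 48, 48, 5, 2.5, 0, 0.9)$frame
  frames <- array(rep(fr, 10), c(96, 96, 10))
  clip <- new("VideoClip", frames = frames, fps = 8)
  det <- detectClip(clip, detectorConfig(background = matrix(0, 96, 96)))
  traj <- clipToTrajectory(clip, det)
  expect_lt(mean(traj), 0.02)
})

test_that("clip trajectories separate swim-direction content by hue", {
  # full arena geometry: the hue structure of the fused image is what the
  # downstream classifier consumes, so this runs at production frame size
  base <- function(behavior, dir) sceneConfig(
    duration = 2, fps = 10, angularSpeed = 0.5, behavior = behavior,
    eventTime = 1, swimDirection = dir, noiseSigma = 0,
    reflectionProb = 0, seed = 13)
  trajOf <- function(cfg) {
    o <- generateClip(cfg)
    clipToTrajectory(o$clip, detectClip(o$clip))
  }
  trN <- trajOf(base("no_change", "counterclockwise"))
  trC <- trajOf(base("change", "counterclockwise"))
  hN <- trajectoryHueHistogram(trN)
  hC <- trajectoryHueHistogram(trC)
  # single swim direction: one dominant hue family (within +/- 90 degrees)
  expect_gt(mainHueMass(hN, half = 9), 0.95)
  # direction reversal: substantial hue mass leaves the +/- 45 degree
  # window of the dominant direction (the reversed pass shifts and
  # desaturates the fused colors); calibrated on the synthetic generator
  expect_lt(1 - mainHueMass(hN, half = 4), 0.02)
  expect_gt(1 - mainHueMass(hC, half = 4), 0.15)
  # opposite-direction clips land in different hue families
  trR <- trajOf(base("no_change", "clockwise"))
  hR <- trajectoryHueHistogram(trR)
  expect_gt(abs(which.max(hN) - which.max(hR)), 6)
})

test_that("frames without detections contribute black flow, not errors", {
  out <- generateClip(tinyScene(seed = 4))
  det <- detectClip(out$clip)
  detPartial <- det[det$frame > 4, , drop = FALSE]
  traj <- clipToTrajectory(out$clip, detPartial)
  expect_equal(dim(traj), c(256, 256, 3))
  # no detections at all: entirely black image
  trajNone <- clipToTrajectory(out$clip, det[0, , drop = FALSE])
  expect_true(all(trajNone == 0))
  oneFrame <- new("VideoClip",
                  frames = out$clip@frames[, , 1, drop = FALSE], fps = 8)
  expect_error(clipToTrajectory(oneFrame, det), "at least 2")
})

test_that("masked flow is confined to the masks and carries less energy", {
  out <- generateClip(tinyScene(seed = 15))
  clip <- out$clip
  det <- detectClip(clip)
  energy <- function(fl) sum(fl$dx^2 + fl$dy^2)
  shape <- frameSize(clip)
  for (k in c(1, 4, 8)) {
    b <- det[det$frame == k, ][1, ]
    b2 <- det[det$frame == k + 1, ][1, ]
    mm <- buildMask(shape, b); mm2 <- buildMask(shape, b2)
    flM <- denseFlow(applyMask(getFrame(clip, k), mm),
                     applyMask(getFrame(clip, k + 1), mm2),
                     mask = mm | mm2)
    # support contract: zero outside the union of the two masks
    expect_true(all(flM$dx[!(mm | mm2)] == 0))
    expect_true(all(flM$dy[!(mm | mm2)] == 0))
    eMasked <- energy(flM)
    eFull <- energy(denseFlow(getFrame(clip, k), getFrame(clip, k + 1)))
    expect_lte(eMasked, eFull + 1e-9)
    expect_gt(eMasked, 0) # the fish does move
  }
})

test_that("the trajectory stage is deterministic", {
  out <- generateClip(tinyScene(seed = 2, noiseSigma = 3))
  det <- detectClip(out$clip)
  t1 <- clipToTrajectory(out$clip, det)
  t2 <- clipToTrajectory(out$clip, det)
  expect_identical(t1, t2)
})
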