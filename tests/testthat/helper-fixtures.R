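# Small-geometry scene configurations and independent oracles used across
# the unit tests. Fixtures are generated in code; nothing is read from disk.

# A fast scene: 96x96 frames, short clips. Defaults are noise-free so
# detection oracles are exact; individual tests override nuisance factors.
tinyScene <- function(duration = 1.5, fps = 8, behavior = "no_change",
                      eventTime = 0.75, angularSpeed = 1.2, noiseSigma = 0,
                      reflectionProb = 0, seed = 1L, ...) {
  sceneConfig(width = 96L, height = 96L, arenaCenter = c(48, 48),
              arenaRadius = 42, postRadius = 8, fishAxes = c(5, 2.5),
              duration = duration, fps = fps, behavior = behavior,
              eventTime = eventTime, angularSpeed = angularSpeed,
              noiseSigma = noiseSigma, reflectionProb = reflectionProb,
              seed = seed, ...)
}

# Pixel-set IoU oracle on an integer grid: rasterize both half-open boxes
# over unit pixels and count memberships.
pixelIoU <- function(a, b, grid = 20) {
  cells <- expand.grid(x = seq_len(grid) - 1, y = seq_len(grid) - 1)
  inA <- cells$x >= a[1] & cells$x < a[3] & cells$y >= a[2] & cells$y < a[4]
  inB <- cells$x >= b[1] & cells$x < b[3] & cells$y >= b[2] & cells$y < b[4]
  inter <- sum(inA & inB)
  uni <- sum(inA | inB)
  if (uni == 0) 0 else inter / uni
}

# Brute-force disk pixel count: scan every pixel of an h x w frame.
diskPixelCount <- function(h, w, cx, cy, r) {
  n <- 0L
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((j - 1 - cx)^2 + (i - 1 - cy)^2 <= r^2) n <- n + 1L
  n
}

# Independent AP oracle: for every prefix of the confidence-ranked list,
# recompute the greedy matching from scratch; then use the per-recall-level
# formulation AP = (1/T) * sum over truth levels of the maximum precision
# achieved at or beyond that recall.
apOracle <- function(detections, truth, iouThreshold) {
  nT <- nrow(truth)
  if (nrow(detections) == 0 || nT == 0) return(0)
  det <- detections[order(-detections$confidence), , drop = FALSE]
  n <- nrow(det)
  tpAt <- integer(n)
  for (k in seq_len(n)) {
    used <- rep(FALSE, nT)
    tp <- 0L
    for (i in seq_len(k)) {
      cand <- which(truth$frame == det$frame[i] & !used)
      if (length(cand)) {
        ious <- vapply(cand, function(j) pixelIoU(
          as.numeric(det[i, c("x_min", "y_min", "x_max", "y_max")]),
          as.numeric(truth[j, c("x_min", "y_min", "x_max", "y_max")]),
          grid = 40), numeric(1))
        best <- cand[which.max(ious)]
        if (max(ious) >= iouThreshold - 1e-9) {
          tp <- tp + 1L
          used[best] <- TRUE
        }
      }
    }
    tpAt[k] <- tp
  }
  prec <- tpAt / seq_len(n)
  total <- 0
  for (lev in seq_len(nT)) {
    ok <- tpAt >= lev
    total <- total + if (any(ok)) max(prec[ok]) else 0
  }
  total / nT
}

# Random detection/truth instances on a 40x40 grid for oracle comparisons.
randomApInstance <- function(seed) {
  set.seed(seed)
  nT <- sample(0:3, 1)
  nD <- sample(1:5, 1)
  truth <- if (nT > 0) {
    data.frame(frame = sample(seq_len(nT)), x_min = 0, y_min = 0,
               x_max = 0, y_max = 0)
  } else data.frame(frame = integer(0), x_min = numeric(0),
                    y_min = numeric(0), x_max = numeric(0),
                    y_max = numeric(0))
  for (i in seq_len(nT)) {
    x0 <- sample(0:30, 1); y0 <- sample(0:30, 1)
    truth[i, 2:5] <- c(x0, y0, x0 + sample(3:10, 1), y0 + sample(3:10, 1))
  }
  det <- data.frame(frame = sample(seq_len(max(nT, 3)), nD, replace = TRUE),
                    x_min = 0, y_min = 0, x_max = 0, y_max = 0,
                    confidence = round(runif(nD), 3))
  for (i in seq_len(nD)) {
    if (nT > 0 && det$frame[i] %in% truth$frame && runif(1) < 0.6) {
      base <- truth[truth$frame == det$frame[i], ]
      jit <- sample(-3:3, 4, replace = TRUE)
      box <- as.numeric(base[1, 2:5]) + jit
      if (box[1] >= box[3]) box[3] <- box[1] + 2
      if (box[2] >= box[4]) box[4] <- box[2] + 2
      det[i, 2:5] <- box
    } else {
      x0 <- sample(0:30, 1); y0 <- sample(0:30, 1)
      det[i, 2:5] <- c(x0, y0, x0 + sample(3:10, 1), y0 + sample(3:10, 1))
    }
  }
  list(det = det, truth = truth)
}

# Trajectory image of a freshly generated scene under a model's settings.
clipTrajectoryFor <- function(model, cfg) {
  clip <- generateClip(cfg)$clip
  det <- detectClip(clip, model@config$detector)
  clipToTrajectory(clip, det, model@config$flow,
                   radius = model@config$radius,
                   magCap = model@config$magCap,
                   method = model@config$fusion)
}

# Hue mass inside +/- `half` bins of the dominant bin (circular window).
mainHueMass <- function(hist, half = 9) {
  if (sum(hist) == 0) return(0)
  top <- which.max(hist)
  n <- length(hist)
  sum(hist[((top - 1 + (-half:half)) %% n) + 1])
}
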