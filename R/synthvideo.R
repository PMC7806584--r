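#' Create a scene configuration for the synthetic arena generator
#'
#' The generator emulates an overhead infrared recording of the escape-response
#' assay: a dark circular container with a central post, one bright elliptical
#' fish-like blob swimming along the wall at constant angular speed, and an
#' optional behavioral event at `eventTime` where the swim direction reverses
#' and the speed is multiplied (the escape response: the fish turns and
#' rapidly swims away). Nuisance factors mirror the failure modes of real
#' footage: low light, per-frame spurious reflections mirrored across the
#' arena wall, and Gaussian sensor noise.
#'
#' @param width,height frame size in pixels (default 256x256, so trajectory
#'   images need no resize).
#' @param fps frames per second (default 25).
#' @param duration clip length in seconds (default 4, the unit the
#'   classifiers consume).
#' @param arenaCenter arena center (x, y), pixels; default frame center.
#' @param arenaRadius,postRadius arena and post radii, pixels.
#' @param fishAxes ellipse semi-axes (major, minor), pixels.
#' @param swimRadius fish orbit radius; `NA` = wall-hugging default
#'   (`arenaRadius - major - 6`).
#' @param startAngle initial angular position, radians.
#' @param angularSpeed angular speed magnitude, radians/second.
#' @param swimDirection `"counterclockwise"` (default) or `"clockwise"`.
#' @param behavior `"no_change"` (default) or `"change"`.
#' @param eventTime event time, seconds (only used when behavior is
#'   `"change"`).
#' @param speedMultiplier speed factor applied at the event (default 2).
#' @param lightLevel global brightness in [0, 1].
#' @param reflectionProb per-frame probability of a mirrored reflection blob.
#' @param noiseSigma Gaussian noise std in 8-bit gray levels.
#' @param seed integer RNG seed; the full frame sequence is a deterministic
#'   function of the configuration.
#' @return a validated [SceneConfig-class]
#' @examples
#' cfg <- sceneConfig(duration = 1, fps = 10, noiseSigma = 0)
#' out <- generateClip(cfg)
#' nFrames(out$clip)
#' @export
sceneConfig <- function(width = 256L, height = 256L, fps = 25, duration = 4,
                        arenaCenter = c(width / 2, height / 2),
                        arenaRadius = 112, postRadius = 22,
                        fishAxes = c(9, 4.5), swimRadius = NA_real_,
                        startAngle = 0, angularSpeed = 1.2,
                        swimDirection = c("counterclockwise", "clockwise"),
                        behavior = c("no_change", "change"), eventTime = 2,
                        speedMultiplier = 2, lightLevel = 0.85,
                        reflectionProb = 0.02, noiseSigma = 3, seed = 1L) {
  swimDirection <- match.arg(swimDirection)
  behavior <- match.arg(behavior)
  new("SceneConfig", width = as.integer(width), height = as.integer(height),
      fps = fps, duration = duration, arenaCenter = as.numeric(arenaCenter),
      arenaRadius = arenaRadius, postRadius = postRadius,
      fishAxes = as.numeric(fishAxes), swimRadius = swimRadius,
      startAngle = startAngle, angularSpeed = angularSpeed,
      swimDirection = swimDirection, behavior = behavior,
      eventTime = eventTime, speedMultiplier = speedMultiplier,
      lightLevel = lightLevel, reflectionProb = reflectionProb,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

# Effective orbit radius for a config.
swimRadiusOf <- function(config) {
  if (!is.na(config@swimRadius)) return(config@swimRadius)
  r <- config@arenaRadius - max(config@fishAxes) - 6
  lo <- config@postRadius + max(config@fishAxes)
  max(r, lo)
}

# Paint a filled ellipse into `frame` (matrix), returning the frame and the
# 0-based half-open bounding box of the painted pixels (or NULL if fully
# outside the frame). Intensities are written with pmax so overlapping
# shapes keep the brighter value.
paintEllipse <- function(frame, cx, cy, a, b, phi, value) {
  h <- nrow(frame); w <- ncol(frame)
  ext <- max(a, b) + 1
  cLo <- max(1, floor(cx - ext) + 1); cHi <- min(w, ceiling(cx + ext) + 1)
  rLo <- max(1, floor(cy - ext) + 1); rHi <- min(h, ceiling(cy + ext) + 1)
  if (cLo > cHi || rLo > rHi) return(list(frame = frame, box = NULL))
  cols <- cLo:cHi
  rows <- rLo:rHi
  # pixel j (1-based) is addressed by 0-based coordinate j - 1
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  dx <- px - cx; dy <- py - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  inside <- u * u + v * v <= 1
  if (!any(inside)) return(list(frame = frame, box = NULL))
  sub <- frame[rows, cols, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  frame[rows, cols] <- sub
  icol <- rep(cols, each = length(rows))[inside]
  irow <- rep(rows, times = length(cols))[inside]
  box <- c(x_min = min(icol) - 1, y_min = min(irow) - 1,
           x_max = max(icol), y_max = max(irow))
  list(frame = frame, box = box)
}

#' Generate one synthetic arena clip with ground truth
#'
#' Renders `duration * fps` frames. When `behavior = "change"`, the signed
#' per-frame angular displacement flips sign exactly once, at the first
#' frame whose timestamp reaches `eventTime`, and its magnitude is scaled by
#' `speedMultiplier`. With zero noise and no reflections the fish is the
#' brightest connected component of every frame and its painted centroid
#' tracks the true center to sub-pixel accuracy, which downstream detection
#' tests rely on.
#'
#' @param config a [SceneConfig-class] from [sceneConfig()]
#' @return list with elements `clip` ([VideoClip-class]) and `track`
#'   ([GroundTruthTrack-class]); the track holds one true box per frame and
#'   the 0/1 clip label (1 = behavioral change).
#' @export
generateClip <- function(config) {
  validObject(config)
  h <- config@height; w <- config@width
  nF <- round(config@duration * config@fps)
  if (nF < 2) stop("clip must contain at least 2 frames")
  L <- config@lightLevel
  ctr <- config@arenaCenter
  rSwim <- swimRadiusOf(config)
  dir <- if (config@swimDirection == "counterclockwise") 1 else -1
  a <- config@fishAxes[1]; b <- config@fishAxes[2]

  # static background: dim floor outside the arena, brighter arena interior,
  # dark central post (all scaled by the light level)
  px <- rep(seq_len(w) - 1, each = h)
  py <- rep(seq_len(h) - 1, times = w)
  d2 <- (px - ctr[1])^2 + (py - ctr[2])^2
  bg <- matrix(0.02 * L, h, w)
  bg[d2 <= config@arenaRadius^2] <- 0.16 * L
  bg[d2 <= config@postRadius^2] <- 0.05 * L

  # per-frame angular increments; sign flip + speed scale at the event
  tIdx <- (seq_len(nF) - 1) / config@fps
  omega <- rep(dir * config@angularSpeed, nF)
  if (config@behavior == "change") {
    after <- tIdx >= config@eventTime
    omega[after] <- -dir * config@angularSpeed * config@speedMultiplier
  }
  theta <- config@startAngle + c(0, cumsum(omega[-nF])) / config@fps

  withSeed(config@seed, {
    frames <- array(0, dim = c(h, w, nF))
    boxes <- matrix(0, nF, 4)
    centers <- matrix(0, nF, 2)
    sigma <- config@noiseSigma / 255
    fishVal <- 0.95 * L
    reflVal <- 0.38 * L
    rRefl <- 2 * config@arenaRadius - rSwim
    for (k in seq_len(nF)) {
      cx <- ctr[1] + rSwim * cos(theta[k])
      cy <- ctr[2] + rSwim * sin(theta[k])
      phi <- theta[k] + dir * pi / 2
      fr <- bg
      if (config@reflectionProb > 0 &&
          runif(1) < config@reflectionProb) {
        rx <- ctr[1] + rRefl * cos(theta[k])
        ry <- ctr[2] + rRefl * sin(theta[k])
        fr <- paintEllipse(fr, rx, ry, a, b, phi, reflVal)$frame
      }
      pe <- paintEllipse(fr, cx, cy, a, b, phi, fishVal)
      fr <- pe$frame
      if (is.null(pe$box))
        stop("configuration error: fish rendered outside the frame")
      if (sigma > 0)
        fr <- fr + matrix(rnorm(h * w, 0, sigma), h, w)
      frames[, , k] <- clamp01(fr)
      boxes[k, ] <- pe$box
      centers[k, ] <- c(cx, cy)
    }
    clip <- new("VideoClip", frames = frames, fps = config@fps)
    track <- new("GroundTruthTrack",
                 boxes = data.frame(frame = seq_len(nF),
                                    x_min = boxes[, 1], y_min = boxes[, 2],
                                    x_max = boxes[, 3], y_max = boxes[, 4]),
                 centers = centers,
                 label = if (config@behavior == "change") 1L else 0L)
    list(clip = clip, track = track)
  })
}

#' Build a labeled synthetic dataset manifest
#'
#' Derives `nClips` per-clip configurations from a base configuration:
#' `round(nClips * classBalance)` clips get the behavioral-change label 1 and
#' the remainder label 0. Nuisance parameters (angular speed, start angle,
#' swim direction, light level, event time) are varied per clip, and each
#' clip receives a sub-seed derived deterministically from `seed`, so the
#' same master seed always yields the same collection.
#'
#' Clips are returned lazily as configurations rather than rendered frames
#' (a rendered 160-clip corpus at the default geometry would not fit in
#' memory); render any element with [generateClip()], or pass the manifest
#' directly to [runTraining()], which renders and discards clips one at a
#' time.
#'
#' @param nClips number of clips (>= 2)
#' @param classBalance fraction of clips labeled 1, in (0, 1)
#' @param baseConfig template [SceneConfig-class]
#' @param seed master seed
#' @param vary vary nuisance parameters per clip (default TRUE)
#' @return list with `configs` (list of [SceneConfig-class]), `labels`
#'   (integer vector) and `seed`
#' @examples
#' ds <- makeDataset(4, 0.5, sceneConfig(duration = 1, fps = 10), seed = 7)
#' table(ds$labels)
#' @export
makeDataset <- function(nClips, classBalance = 0.5,
                        baseConfig = sceneConfig(), seed = 1L, vary = TRUE) {
  if (nClips < 2) stop("nClips must be >= 2")
  if (classBalance <= 0 || classBalance >= 1)
    stop("classBalance must be in (0, 1)")
  nPos <- round(nClips * classBalance)
  labels <- c(rep(1L, nPos), rep(0L, nClips - nPos))
  configs <- withSeed(seed, {
    lapply(seq_len(nClips), function(i) {
      cfg <- baseConfig
      cfg@behavior <- if (labels[i] == 1L) "change" else "no_change"
      if (vary) {
        cfg@angularSpeed <- baseConfig@angularSpeed * runif(1, 0.8, 1.25)
        cfg@startAngle <- runif(1, 0, 2 * pi)
        cfg@swimDirection <- sample(c("clockwise", "counterclockwise"), 1)
        cfg@lightLevel <- min(1, baseConfig@lightLevel * runif(1, 0.8, 1.15))
        cfg@eventTime <- runif(1, 0.3, 0.7) * cfg@duration
      }
      cfg@seed <- sample.int(2147483646L, 1)
      validObject(cfg)
      cfg
    })
  })
  list(configs = configs, labels = labels, seed = as.integer(seed))
}
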