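#' Scene configuration for the synthetic arena generator
#'
#' Describes one synthetic clip: the test arena geometry (a dark circular
#' container with a central post, viewed from above under infrared-like
#' illumination), the kinematics of a single elliptical fish-like blob
#' swimming along the wall, an optional behavioral event (direction reversal
#' plus speed change, emulating the visually-mediated escape response), and
#' nuisance factors (global light level, spurious surface reflections,
#' sensor noise).
#'
#' @slot width,height frame size in pixels.
#' @slot fps frames per second.
#' @slot duration clip duration in seconds.
#' @slot arenaCenter numeric length-2, arena center (x, y) in pixels,
#'   0-based continuous coordinates.
#' @slot arenaRadius,postRadius arena wall and central-post radii (pixels).
#' @slot fishAxes numeric length-2 ellipse semi-axes (major, minor) pixels.
#' @slot swimRadius distance of the fish center from the arena center; `NA`
#'   picks a wall-hugging default.
#' @slot startAngle initial angular position (radians).
#' @slot angularSpeed magnitude of the angular velocity (radians/second).
#' @slot swimDirection `"clockwise"` or `"counterclockwise"`.
#' @slot behavior `"change"` (escape event at `eventTime`) or `"no_change"`.
#' @slot eventTime time of the escape event in seconds.
#' @slot speedMultiplier factor applied to the angular speed at the event.
#' @slot lightLevel global brightness scale in [0, 1].
#' @slot reflectionProb per-frame probability of a spurious mirrored blob.
#' @slot noiseSigma Gaussian pixel noise, in 8-bit gray levels.
#' @slot seed integer seed; identical configs give bit-identical clips.
#' @seealso [sceneConfig()], [generateClip()]
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    width = "integer", height = "integer", fps = "numeric",
    duration = "numeric", arenaCenter = "numeric", arenaRadius = "numeric",
    postRadius = "numeric", fishAxes = "numeric", swimRadius = "numeric",
    startAngle = "numeric", angularSpeed = "numeric",
    swimDirection = "character", behavior = "character",
    eventTime = "numeric", speedMultiplier = "numeric",
    lightLevel = "numeric", reflectionProb = "numeric",
    noiseSigma = "numeric", seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@width < 16 || object@height < 16)
    msg <- c(msg, "frame must be at least 16x16 pixels")
  if (object@fps <= 0 || object@duration <= 0)
    msg <- c(msg, "fps and duration must be positive")
  if (round(object@duration * object@fps) < 2)
    msg <- c(msg, "clip must contain at least 2 frames (duration*fps >= 2)")
  if (!object@swimDirection %in% c("clockwise", "counterclockwise"))
    msg <- c(msg, "swimDirection must be clockwise or counterclockwise")
  if (!object@behavior %in% c("change", "no_change"))
    msg <- c(msg, "behavior must be change or no_change")
  if (object@behavior == "change" &&
      (object@eventTime <= 0 || object@eventTime >= object@duration))
    msg <- c(msg, "eventTime must fall strictly inside the clip")
  if (object@lightLevel < 0 || object@lightLevel > 1)
    msg <- c(msg, "lightLevel must be in [0, 1]")
  if (object@reflectionProb < 0 || object@reflectionProb > 1)
    msg <- c(msg, "reflectionProb must be in [0, 1]")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  major <- max(object@fishAxes)
  lo <- object@postRadius + major
  hi <- object@arenaRadius - major
  if (lo >= hi)
    msg <- c(msg, "fish does not fit in the annulus between post and wall")
  r <- object@swimRadius
  if (!is.na(r) && (r < lo || r > hi))
    msg <- c(msg, sprintf("swimRadius must lie in [%.1f, %.1f]", lo, hi))
  cx <- object@arenaCenter[1]; cy <- object@arenaCenter[2]
  if (cx - object@arenaRadius < -1 || cx + object@arenaRadius > object@width ||
      cy - object@arenaRadius < -1 || cy + object@arenaRadius > object@height)
    msg <- c(msg, "arena must fit inside the frame")
  if (length(msg)) msg else TRUE
})

#' An ordered frame sequence with a frame rate
#'
#' Frames are stored as a numeric array `height x width x nframes` with
#' grayscale values in [0, 1] (the recordings this emulates are infrared and
#' effectively single-channel; color input is collapsed on ingestion).
#'
#' @slot frames numeric array (h, w, t) in [0, 1].
#' @slot fps frames per second.
#' @exportClass VideoClip
setClass("VideoClip",
  representation(frames = "array", fps = "numeric"))

setValidity("VideoClip", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("frames must be an (h, w, t) array")
  if (object@fps <= 0) return("fps must be positive")
  rng <- range(object@frames)
  if (!all(is.finite(rng))) return("frames contain non-finite values")
  if (rng[1] < 0 || rng[2] > 1) return("frame values must lie in [0, 1]")
  TRUE
})

#' Ground truth for one synthetic clip
#'
#' One axis-aligned box and one true center per frame, plus the clip-level
#' behavior label (1 = behavioral change). Boxes use 0-based half-open pixel
#' coordinates, so `area = (x_max - x_min) * (y_max - y_min)`.
#'
#' @slot boxes data.frame with columns `frame`, `x_min`, `y_min`, `x_max`,
#'   `y_max` (one row per frame, `frame` is 1-based).
#' @slot centers numeric matrix (t, 2) of true fish centers (x, y).
#' @slot label integer 0/1 clip label.
#' @exportClass GroundTruthTrack
setClass("GroundTruthTrack",
  representation(boxes = "data.frame", centers = "matrix", label = "integer"))

setValidity("GroundTruthTrack", function(object) {
  need <- c("frame", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(object@boxes)))
    return("boxes must have columns frame, x_min, y_min, x_max, y_max")
  if (nrow(object@boxes) != nrow(object@centers))
    return("one box and one center per frame required")
  if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
  if (any(object@boxes$x_min >= object@boxes$x_max) ||
      any(object@boxes$y_min >= object@boxes$y_max))
    return("boxes must satisfy x_min < x_max and y_min < y_max")
  TRUE
})

#' Single-hidden-layer autoencoder for trajectory images
#'
#' Encoder \eqn{y = s(Wx + b)} and decoder \eqn{z = s(W'y + b')} over
#' flattened trajectory images \eqn{x \in [0,1]^d}, with nonlinearity
#' \eqn{s} either sigmoid or ReLU. The latent code `y` (default 64 values)
#' is the feature vector consumed by the classifiers.
#'
#' @slot W encoder weights, `d x dLatent`.
#' @slot b encoder bias, length `dLatent`.
#' @slot Wp decoder weights, `dLatent x d`.
#' @slot bp decoder bias, length `d`.
#' @slot config the [autoencoderConfig()] list used for training.
#' @slot inputDim integer length-3 image dimensions (h, w, channels).
#' @slot lossHistory per-epoch training reconstruction loss.
#' @slot trained logical; `FALSE` for a freshly initialized model.
#' @exportClass Autoencoder
setClass("Autoencoder",
  representation(W = "matrix", b = "numeric", Wp = "matrix", bp = "numeric",
                 config = "list", inputDim = "integer",
                 lossHistory = "numeric", trained = "logical"))

#' Gaussian mixture model parameters (one behavior class)
#'
#' A density \eqn{p(x) = \sum_i \phi_i N(x | \mu_i, \sigma_i)} fitted by
#' expectation maximization; used as a class-conditional generative sampler
#' for feature-space data augmentation.
#'
#' @slot weights mixture weights, length K, summing to 1.
#' @slot means K x d component means.
#' @slot variances K x d diagonal variances (`covType = "diagonal"`), or
#'   unused when `covType = "full"`.
#' @slot covariances list of K d x d matrices when `covType = "full"`.
#' @slot covType `"diagonal"` or `"full"`.
#' @slot logLik per-iteration EM log-likelihood trace (non-decreasing).
#' @slot classLabel optional 0/1 class this mixture models (NA otherwise).
#' @slot seed integer seed used for initialization.
#' @exportClass GMMParams
setClass("GMMParams",
  representation(weights = "numeric", means = "matrix",
                 variances = "matrix", covariances = "list",
                 covType = "character", logLik = "numeric",
                 classLabel = "integer", seed = "integer"))

setValidity("GMMParams", function(object) {
  K <- length(object@weights)
  if (K < 1) return("at least one component required")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("mixture weights must sum to 1")
  if (any(object@weights < 0)) return("mixture weights must be >= 0")
  if (nrow(object@means) != K) return("means must have K rows")
  if (object@covType == "diagonal") {
    if (!all(dim(object@variances) == dim(object@means)))
      return("diagonal variances must match means in shape")
    if (any(object@variances <= 0)) return("variances must be positive")
  }
  TRUE
})

#' A fitted binary behavior classifier
#'
#' Wraps one of the five supported backends (linear SVM, L2-regularized
#' logistic regression, Gaussian naive Bayes, decision tree, random forest)
#' together with the training-fold standardization used for the margin-based
#' models. Predictions are hard labels in {0, 1}; a tied decision resolves
#' to 0 ("no change").
#'
#' @slot kind classifier kind.
#' @slot fit the backend model object.
#' @slot config the [classifierConfig()] used.
#' @slot center,scale feature standardization (numeric(0) when unused).
#' @slot featureDim expected feature dimension.
#' @exportClass FishClassifier
setClass("FishClassifier",
  representation(kind = "character", fit = "ANY", config = "list",
                 center = "numeric", scale = "numeric",
                 featureDim = "integer"))

#' Cross-validation evaluation report
#'
#' Per-fold and aggregated accuracy, precision, recall and F1 from repeated
#' random-subsampling validation (independent stratified 90/10 splits by
#' default).
#'
#' @slot folds data.frame, one row per fold: metrics plus split sizes.
#' @slot means,sds named numeric vectors over the four metrics.
#' @slot kind classifier kind evaluated.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(folds = "data.frame", means = "numeric", sds = "numeric",
                 kind = "character"))

setValidity("EvalReport", function(object) {
  m <- c("accuracy", "precision", "recall", "f1")
  if (!all(m %in% names(object@means))) return("means must cover all metrics")
  vals <- unlist(object@folds[, m])
  if (length(vals) && (any(vals < -1e-12) || any(vals > 1 + 1e-12)))
    return("metrics must lie in [0, 1]")
  if (any(object@sds < 0)) return("standard deviations must be >= 0")
  TRUE
})

#' Trained end-to-end pipeline bundle
#'
#' Everything needed to turn a raw clip into a verdict: detector settings,
#' the trained autoencoder, the two class-conditional GMMs (when
#' augmentation was used) and the fitted classifier, plus the pipeline
#' configuration and seed for provenance.
#'
#' @slot autoencoder the trained [Autoencoder-class].
#' @slot gmmNeg,gmmPos class-conditional [GMMParams-class] (or NULL).
#' @slot classifier the fitted [FishClassifier-class].
#' @slot config the [pipelineConfig()] used for training.
#' @slot seed master seed.
#' @slot summary list of training diagnostics.
#' @exportClass FishFlowModel
setClass("FishFlowModel",
  representation(autoencoder = "Autoencoder", gmmNeg = "ANY", gmmPos = "ANY",
                 classifier = "FishClassifier", config = "list",
                 seed = "integer", summary = "list"))
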