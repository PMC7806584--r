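#' @describeIn VideoClip-class number of frames
#' @param object,x a `VideoClip`
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "VideoClip", function(x) dim(x@frames)[3])

#' Frames-per-second accessor
#' @param x a [VideoClip-class]
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname fps
#' @export
setMethod("fps", "VideoClip", function(x) x@fps)

#' Frame size accessor
#' @param x a [VideoClip-class]
#' @return integer `(height, width)`
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))

#' @rdname frameSize
#' @export
setMethod("frameSize", "VideoClip", function(x) dim(x@frames)[1:2])

#' Extract a single frame
#' @param x a [VideoClip-class]
#' @param i frame index (1-based)
#' @return numeric matrix (h, w) in [0, 1]
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "VideoClip", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@frames)[3])
  x@frames[, , i]
})

#' Latent dimension accessor
#' @param x an [Autoencoder-class]
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' @rdname latentDim
#' @export
setMethod("latentDim", "Autoencoder", function(x) ncol(x@W))

#' Duration in seconds
#' @param x a [VideoClip-class]
#' @export
setGeneric("clipDuration", function(x) standardGeneric("clipDuration"))

#' @rdname clipDuration
#' @export
setMethod("clipDuration", "VideoClip", function(x) dim(x@frames)[3] / x@fps)

setMethod("show", "VideoClip", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoClip: %d frames of %dx%d @ %.3g fps (%.2f s)\n",
              d[3], d[1], d[2], object@fps, d[3] / object@fps))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %dx%d @ %g fps, %g s | arena r=%g post r=%g | %s, %s\n",
    object@width, object@height, object@fps, object@duration,
    object@arenaRadius, object@postRadius, object@swimDirection,
    object@behavior))
  if (object@behavior == "change")
    cat(sprintf("  escape at t=%g s (speed x%g)\n", object@eventTime,
                object@speedMultiplier))
  cat(sprintf("  light=%g, reflectionProb=%g, noiseSigma=%g, seed=%d\n",
              object@lightLevel, object@reflectionProb, object@noiseSigma,
              object@seed))
})

setMethod("show", "GroundTruthTrack", function(object) {
  cat(sprintf("GroundTruthTrack: %d frames, label=%d\n",
              nrow(object@boxes), object@label))
})

setMethod("show", "Autoencoder", function(object) {
  cat(sprintf("Autoencoder: %d -> %d (%s, %s)%s\n",
              nrow(object@W), ncol(object@W),
              object@config$nonlinearity, object@config$loss,
              if (object@trained) sprintf(", final loss %.4g",
                  object@lossHistory[length(object@lossHistory)])
              else " [untrained]"))
})

setMethod("show", "GMMParams", function(object) {
  cat(sprintf("GMMParams: K=%d, d=%d, %s covariance%s\n",
              length(object@weights), ncol(object@means), object@covType,
              if (!is.na(object@classLabel))
                sprintf(", class %d", object@classLabel) else ""))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
})

setMethod("show", "FishClassifier", function(object) {
  cat(sprintf("FishClassifier: %s (%d features)\n", object@kind,
              object@featureDim))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s, %d folds)\n", object@kind,
              nrow(object@folds)))
  for (m in c("accuracy", "precision", "recall", "f1"))
    cat(sprintf("  %-9s %.3f (+/- %.3f)\n", m, object@means[[m]],
                object@sds[[m]]))
})

setMethod("show", "FishFlowModel", function(object) {
  cat("FishFlowModel\n")
  cat(sprintf("  autoencoder: %d-dim latent\n", ncol(object@autoencoder@W)))
  cat(sprintf("  augmentation: %s\n",
              if (!is.null(object@gmmPos)) "2 class-conditional GMMs"
              else "none"))
  cat(sprintf("  classifier: %s\n", object@classifier@kind))
})
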