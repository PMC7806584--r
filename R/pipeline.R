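#' Pipeline configuration
#'
#' Nested per-stage settings for the end-to-end tool. Clips are the unit of
#' classification; raw videos are segmented into consecutive
#' non-overlapping clips of `clipLength` seconds (default 4, the duration
#' over which a behavioral change is judged).
#'
#' @param clipLength clip length in seconds (> 0).
#' @param detector a [detectorConfig()].
#' @param flow a [flowConfig()].
#' @param radius fish-mask radius, pixels.
#' @param magCap flow-image magnitude cap, pixels/frame.
#' @param fusion trajectory fusion operator, `"max"` or `"sum"`.
#' @param autoencoder an [autoencoderConfig()].
#' @param gmmK mixture components per class.
#' @param nPerClass synthetic samples per class when augmenting.
#' @param classifier a [classifierConfig()].
#' @param augment train the classifier on GMM-sampled synthetic features
#'   (default TRUE).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(clipLength = 4, detector = detectorConfig(),
                           flow = flowConfig(), radius = 10, magCap = 10,
                           fusion = c("max", "sum"),
                           autoencoder = autoencoderConfig(),
                           gmmK = 2, nPerClass = 10000L,
                           classifier = classifierConfig("decision_tree"),
                           augment = TRUE, seed = 1L) {
  fusion <- match.arg(fusion)
  if (clipLength <= 0) stop("clipLength must be positive")
  structure(list(clipLength = clipLength, detector = detector, flow = flow,
                 radius = radius, magCap = magCap, fusion = fusion,
                 autoencoder = autoencoder, gmmK = gmmK,
                 nPerClass = as.integer(nPerClass), classifier = classifier,
                 augment = augment, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Segment a video into fixed-length clips
#'
#' Consecutive, non-overlapping clips of `clipLength` seconds; a trailing
#' remainder shorter than `clipLength` is dropped with a warning.
#'
#' @param video a [VideoClip-class] of any length
#' @param clipLength clip length in seconds
#' @return list of [VideoClip-class] objects
#' @export
segmentVideo <- function(video, clipLength = 4) {
  if (clipLength <= 0) stop("clipLength must be positive")
  perClip <- round(clipLength * fps(video))
  if (perClip < 2) stop("clipLength too short for this frame rate")
  t <- nFrames(video)
  nClips <- t %/% perClip
  if (nClips < 1) stop("video shorter than one clip")
  if (t %% perClip != 0)
    warning(sprintf("dropping %d trailing frames (< clipLength)",
                    t %% perClip))
  lapply(seq_len(nClips), function(i) {
    idx <- ((i - 1) * perClip + 1):(i * perClip)
    new("VideoClip", frames = video@frames[, , idx, drop = FALSE],
        fps = fps(video))
  })
}

# Render-or-pass-through: accepts VideoClip or SceneConfig.
materializeClip <- function(x) {
  if (is(x, "VideoClip")) return(x)
  if (is(x, "SceneConfig")) return(generateClip(x)$clip)
  stop("expected a VideoClip or SceneConfig")
}

# One clip -> trajectory image under a pipeline config.
clipTrajectory <- function(clip, config) {
  det <- detectClip(clip, config$detector)
  clipToTrajectory(clip, det, config$flow, radius = config$radius,
                   magCap = config$magCap, method = config$fusion)
}

#' Train the end-to-end pipeline
#'
#' Runs detection, masking, flow and fusion per clip, trains the
#' autoencoder on the resulting trajectory images, encodes them to feature
#' vectors, optionally fits the two class-conditional GMMs and samples the
#' synthetic training set, and fits the classifier. Clips may be given as
#' rendered [VideoClip-class] objects or as [SceneConfig-class] entries
#' (e.g. a [makeDataset()] manifest), which are rendered one at a time and
#' discarded.
#'
#' @param clips list of [VideoClip-class] or [SceneConfig-class]
#' @param labels 0/1 vector, one label per clip, both classes present
#' @param config a [pipelineConfig()]
#' @param verbose log stage progress to stderr
#' @return a [FishFlowModel-class]
#' @export
runTraining <- function(clips, labels, config = pipelineConfig(),
                        verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(clips) != length(labels)) stop("one label per clip required")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  say <- function(...) if (verbose) message(sprintf(...))
  say("computing trajectory images for %d clips", length(clips))
  feats <- NULL
  images <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    clip <- materializeClip(clips[[i]])
    images[[i]] <- clipTrajectory(clip, config)
    if (verbose && i %% 20 == 0) say("  %d/%d clips", i, length(clips))
  }
  aeCfg <- config$autoencoder
  aeCfg$seed <- deriveSeed(config$seed, 101)
  say("training autoencoder (latent %d)", aeCfg$latentDim)
  ae <- trainAutoencoder(images, aeCfg)
  feats <- encodeTrajectory(ae, images)
  gmmNeg <- NULL; gmmPos <- NULL
  if (config$augment) {
    say("fitting class-conditional GMMs and sampling %d/class",
        config$nPerClass)
    aug <- augmentDataset(feats, labels, nPerClass = config$nPerClass,
                          K = config$gmmK,
                          seed = deriveSeed(config$seed, 202))
    trainX <- aug$features; trainY <- aug$labels
    gmmNeg <- aug$gmmNeg; gmmPos <- aug$gmmPos
  } else {
    trainX <- feats; trainY <- labels
  }
  clfCfg <- config$classifier
  clfCfg$seed <- deriveSeed(config$seed, 303)
  say("training %s classifier on %d vectors", clfCfg$kind, nrow(trainX))
  clf <- trainClassifier(trainX, trainY, clfCfg)
  new("FishFlowModel", autoencoder = ae, gmmNeg = gmmNeg, gmmPos = gmmPos,
      classifier = clf, config = unclass(config),
      seed = config$seed,
      summary = list(nClips = length(clips),
                     classBalance = mean(labels),
                     nTrainingVectors = nrow(trainX),
                     augmented = config$augment))
}

#' Run inference on a video
#'
#' Segments the video into clips, computes each clip's trajectory image and
#' feature vector, and emits one verdict per clip. A clip in which no fish
#' was detected in any frame gets label 0 and a `no_detection` flag rather
#' than an error; a clip that fails outright is flagged `error` and the
#' batch continues.
#'
#' @param video a [VideoClip-class] (or a list of pre-segmented clips)
#' @param model a [FishFlowModel-class] from [runTraining()]
#' @return data.frame with `clip_id`, `start_s`, `end_s`, `label`, `tag`
#'   (`"behavioral change"` / `"no change"`), `flag`
#' @export
runInference <- function(video, model) {
  config <- model@config
  clips <- if (is.list(video)) video
           else segmentVideo(video, config$clipLength)
  durations <- vapply(clips, function(cl)
    tryCatch(nFrames(cl) / fps(cl), error = function(e) config$clipLength),
    numeric(1))
  starts <- cumsum(c(0, durations[-length(durations)]))
  rows <- lapply(seq_along(clips), function(i) {
    start <- starts[i]
    out <- data.frame(clip_id = i, start_s = start, end_s = NA_real_,
                      label = 0L, tag = "no change", flag = "")
    res <- tryCatch({
      clip <- clips[[i]]
      out$end_s <- start + nFrames(clip) / fps(clip)
      det <- detectClip(clip, config$detector)
      if (!nrow(det)) {
        out$flag <- "no_detection"
        return(out)
      }
      traj <- clipToTrajectory(clip, det, config$flow,
                               radius = config$radius,
                               magCap = config$magCap,
                               method = config$fusion)
      feat <- encodeTrajectory(model@autoencoder, traj)
      lab <- predict(model@classifier, feat)
      out$label <- lab
      out$tag <- if (lab == 1L) "behavioral change" else "no change"
      out
    }, error = function(e) {
      out$flag <- paste0("error: ", conditionMessage(e))
      out
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "any_positive") <- any(out$label == 1L)
  out
}
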