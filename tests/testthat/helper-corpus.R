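# Shared study-scale corpus for the acceptance suite: 160 synthetic
# four-second clips (80 escape / 80 no-change) at full arena geometry with
# the generator's default nuisance levels, reduced to trajectory images.
# Building it takes a few minutes, so it is computed once per test run and
# cached for every block that needs it.

corpusCache <- new.env(parent = emptyenv())

acceptanceCorpus <- function() {
  if (!is.null(corpusCache$images)) return(as.list(corpusCache))
  ds <- makeDataset(160, 0.5, sceneConfig(), seed = 2024L)
  cfg <- pipelineConfig()
  images <- vector("list", length(ds$configs))
  for (i in seq_along(ds$configs)) {
    clip <- generateClip(ds$configs[[i]])$clip
    det <- detectClip(clip, cfg$detector)
    images[[i]] <- clipToTrajectory(clip, det, cfg$flow)
  }
  corpusCache$images <- images
  corpusCache$labels <- ds$labels
  as.list(corpusCache)
}
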