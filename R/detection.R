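#' Reference detector configuration
#'
#' The reference backend is classical: a per-pixel temporal-median
#' background model of the clip, absolute differencing, fixed thresholding,
#' connected-component labelling, and one box per retained component with a
#' deterministic surrogate confidence (component area normalized by the
#' largest component's area, so the biggest blob scores 1). A deep detector
#' can be plugged in by supplying a `backend` function with signature
#' `function(frame, config)` returning the same data.frame contract as
#' [detectFrame()].
#'
#' @param threshold absolute-difference threshold on [0, 1] intensities.
#' @param minArea minimum component area in pixels.
#' @param maxDetections cap on detections returned per frame.
#' @param background optional background image (matrix); normally filled in
#'   by [buildBackground()] / [detectClip()].
#' @param backgroundFrames number of evenly spaced frames used for the
#'   temporal median.
#' @param backend optional external detector function (untested adapter
#'   slot for, e.g., a deep detector).
#' @return a list of class `DetectorConfig`
#' @export
detectorConfig <- function(threshold = 0.08, minArea = 12, maxDetections = 5,
                           background = NULL, backgroundFrames = 49,
                           backend = NULL) {
  stopifnot(threshold > 0, minArea >= 1, maxDetections >= 1)
  structure(list(threshold = threshold, minArea = minArea,
                 maxDetections = maxDetections, background = background,
                 backgroundFrames = backgroundFrames, backend = backend),
            class = "DetectorConfig")
}

#' Temporal-median background model of a clip
#'
#' @param clip a [VideoClip-class]
#' @param maxFrames number of evenly spaced frames to use (odd counts avoid
#'   averaging two order statistics)
#' @return background image as an (h, w) matrix
#' @export
buildBackground <- function(clip, maxFrames = 49) {
  t <- nFrames(clip)
  idx <- unique(round(seq(1, t, length.out = min(t, maxFrames))))
  px <- matrix(clip@frames[, , idx, drop = FALSE], ncol = length(idx))
  matrix(cppMedianStack(px), nrow = dim(clip@frames)[1])
}

emptyDetections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), confidence = numeric(0))
}

#' Detect the fish in a single frame
#'
#' Boxes use 0-based half-open pixel coordinates (origin top-left, x right,
#' y down), so `area = (x_max - x_min) * (y_max - y_min)`. Zero detections
#' is a legitimate outcome (an empty data.frame), not an error; only a
#' degenerate frame (empty or non-finite) errors.
#'
#' @param frame numeric matrix or (h, w, c) array in [0, 1]
#' @param config a [detectorConfig()]; its `background` field is subtracted
#'   (a zero background is assumed when NULL, so bright blobs on black are
#'   still found)
#' @return data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `confidence`, sorted by descending confidence
#' @export
detectFrame <- function(frame, config = detectorConfig()) {
  frame <- asGray(frame)
  if (!is.matrix(frame) || nrow(frame) < 2 || ncol(frame) < 2)
    stop("degenerate frame")
  if (!all(is.finite(frame))) stop("frame contains non-finite values")
  if (!is.null(config$backend)) return(config$backend(frame, config))
  bg <- config$background
  diff <- if (is.null(bg)) frame else abs(frame - bg)
  mask <- diff > config$threshold
  if (!any(mask)) return(emptyDetections())
  lab <- EBImage::bwlabel(mask)
  labv <- as.integer(lab)
  idx <- which(labv > 0L)
  ids <- labv[idx]
  areas <- tabulate(ids)
  keep <- which(areas >= config$minArea)
  if (!length(keep)) return(emptyDetections())
  h <- nrow(frame)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  sel <- ids %in% keep
  ids <- ids[sel]; rows <- rows[sel]; cols <- cols[sel]
  uid <- sort(unique(ids))
  stat <- vapply(uid, function(u) {
    w <- ids == u
    c(min(cols[w]) - 1, min(rows[w]) - 1, max(cols[w]), max(rows[w]))
  }, numeric(4))
  conf <- areas[uid] / max(areas[uid])
  out <- data.frame(x_min = stat[1, ], y_min = stat[2, ],
                    x_max = stat[3, ], y_max = stat[4, ],
                    confidence = conf)
  out <- out[order(-out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  head(out, config$maxDetections)
}

#' Detect the fish in every frame of a clip
#'
#' Builds the temporal-median background if the config does not carry one,
#' then applies [detectFrame()] per frame.
#'
#' @param clip a [VideoClip-class]
#' @param config a [detectorConfig()]
#' @return data.frame with a 1-based `frame` column plus the
#'   [detectFrame()] columns; frames without detections contribute no rows
#' @export
detectClip <- function(clip, config = detectorConfig()) {
  if (is.null(config$background))
    config$background <- buildBackground(clip, config$backgroundFrames)
  res <- lapply(seq_len(nFrames(clip)), function(k) {
    d <- detectFrame(clip@frames[, , k], config)
    if (nrow(d)) cbind(frame = k, d) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- cbind(frame = integer(0), emptyDetections())
  rownames(out) <- NULL
  out
}

#' Circular fish mask from a detection
#'
#' The centroid of the bounding box marks the middle of the fish; a disk of
#' `radius` pixels (default 10) around the centroid, clipped to the frame,
#' is the region kept for optical flow. The centroid is rounded to the
#' nearest pixel center (half away from zero). A `NULL` detection gives an
#' empty mask.
#'
#' @param frameShape integer (height, width)
#' @param detection one-row data.frame (or named vector) with `x_min`,
#'   `y_min`, `x_max`, `y_max`, or NULL
#' @param radius disk radius in pixels
#' @return logical (h, w) matrix with attributes `center` (x, y) and
#'   `radius`
#' @export
buildMask <- function(frameShape, detection, radius = 10) {
  if (radius <= 0) stop("radius must be positive")
  h <- frameShape[1]; w <- frameShape[2]
  if (is.null(detection) || (is.data.frame(detection) && !nrow(detection))) {
    m <- matrix(FALSE, h, w)
    attr(m, "center") <- c(NA_real_, NA_real_)
    attr(m, "radius") <- radius
    return(m)
  }
  det <- as.list(detection)
  cx <- (det$x_min + det$x_max) / 2
  cy <- (det$y_min + det$y_max) / 2
  if (det$x_min >= det$x_max || det$y_min >= det$y_max)
    stop("invalid detection box")
  # pixel centers sit at 0-based integer coordinates (1-based column j has
  # center x = j - 1); round the centroid half away from zero
  cx0 <- min(max(floor(cx + 0.5), 0), w - 1)
  cy0 <- min(max(floor(cy + 0.5), 0), h - 1)
  dj <- (seq_len(w) - 1) - cx0
  di <- (seq_len(h) - 1) - cy0
  m <- outer(di^2, dj^2, "+") <= radius^2
  attr(m, "center") <- c(cx0, cy0)
  attr(m, "radius") <- radius
  m
}

#' Intersection over union of two boxes
#'
#' Boxes are 0-based half-open `(x_min, y_min, x_max, y_max)`; IoU is
#' intersection area over union area, in [0, 1].
#'
#' @param a,b numeric length-4 vectors, one-row data.frames, or equal-height
#'   4-column matrices (vectorized row-wise)
#' @return numeric IoU value(s)
#' @export
bboxIoU <- function(a, b) {
  toM <- function(x) {
    if (is.data.frame(x))
      x <- as.matrix(x[, c("x_min", "y_min", "x_max", "y_max")])
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x
  }
  a <- toM(a); b <- toM(b)
  if (any(a[, 1] >= a[, 3]) || any(a[, 2] >= a[, 4]) ||
      any(b[, 1] >= b[, 3]) || any(b[, 2] >= b[, 4]))
    stop("invalid box: need x_min < x_max and y_min < y_max")
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  as.numeric(inter / (areaA + areaB - inter))
}

#' Average precision of ranked detections at one IoU threshold
#'
#' PASCAL-VOC style evaluation for the single-fish setting: detections are
#' ranked by confidence globally (ties keep input order); walking down the
#' ranking, a detection is a true positive if its best-IoU unmatched ground
#' truth box in the same frame reaches the threshold (each truth is
#' consumable once), otherwise a false positive. AP is the area under the
#' interpolated precision-recall curve: all-point (VOC-2010) interpolation
#' by default, the 11-point variant behind a flag.
#'
#' @param detections data.frame with `frame`, box columns and `confidence`
#' @param truth data.frame with `frame` and box columns, at most one row per
#'   frame (single class, single fish)
#' @param iouThreshold IoU needed for a true match
#' @param interpolation `"all"` (VOC-2010) or `"11point"`
#' @return AP in [0, 1]
#' @export
averagePrecision <- function(detections, truth, iouThreshold = 0.5,
                             interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  nTruth <- nrow(truth)
  if (is.null(detections) || nrow(detections) == 0) {
    if (nTruth > 0)
      warning("no detections supplied for a nonempty ground truth; AP = 0")
    return(0)
  }
  if (nTruth == 0) return(0)
  if (anyDuplicated(truth$frame))
    stop("at most one ground-truth box per frame is supported")
  ord <- order(-detections$confidence)
  det <- detections[ord, , drop = FALSE]
  matched <- rep(FALSE, nTruth)
  tp <- numeric(nrow(det))
  for (i in seq_len(nrow(det))) {
    j <- which(truth$frame == det$frame[i] & !matched)
    if (length(j)) {
      ious <- bboxIoU(det[i, ], truth[j, , drop = FALSE])
      best <- which.max(ious)
      if (ious[best] >= iouThreshold) {
        tp[i] <- 1
        matched[j[best]] <- TRUE
      }
    }
  }
  cumTP <- cumsum(tp)
  cumFP <- cumsum(1 - tp)
  prec <- cumTP / (cumTP + cumFP)
  rec <- cumTP / nTruth
  if (interpolation == "11point") {
    pts <- seq(0, 1, by = 0.1)
    vals <- vapply(pts, function(r) {
      ok <- rec >= r
      if (any(ok)) max(prec[ok]) else 0
    }, numeric(1))
    return(mean(vals))
  }
  mrec <- c(0, rec)
  mpre <- c(0, prec)
  # precision envelope (monotone non-increasing from the right)
  for (i in rev(seq_len(length(mpre) - 1)))
    mpre[i] <- max(mpre[i], mpre[i + 1])
  sum(diff(mrec) * mpre[-1])
}

#' Mean average precision over several IoU thresholds
#'
#' With a single class (the fish), mAP equals AP, evaluated per threshold.
#'
#' @inheritParams averagePrecision
#' @param thresholds numeric vector of IoU thresholds
#' @return named numeric vector of AP values, one per threshold
#' @examples
#' truth <- data.frame(frame = 1, x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' det <- cbind(truth, confidence = 1)
#' mapAtThresholds(det, truth)
#' @export
mapAtThresholds <- function(detections, truth,
                            thresholds = c(0.5, 0.75, 0.9),
                            interpolation = c("all", "11point")) {
  if (!length(thresholds)) stop("thresholds must be a nonempty vector")
  interpolation <- match.arg(interpolation)
  out <- vapply(thresholds, function(t)
    averagePrecision(detections, truth, t, interpolation), numeric(1))
  names(out) <- paste0("AP@", formatC(thresholds, format = "g"))
  out
}
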