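#' Dense optical flow configuration
#'
#' Parameters of the polynomial-expansion (Farneback) dense flow: image
#' pyramid scale and depth, the averaging window for the displacement
#' systems, iterations per level, and the Gaussian applicability of the
#' quadratic fit.
#'
#' @param pyrScale pyramid downscale factor per level.
#' @param levels pyramid levels.
#' @param winsize box-averaging window (pixels).
#' @param iters displacement-refinement iterations per level.
#' @param polyN half-size of the polynomial-expansion window.
#' @param polySigma Gaussian std of the applicability.
#' @return list of class `FlowConfig`
#' @export
flowConfig <- function(pyrScale = 0.5, levels = 3, winsize = 15, iters = 3,
                       polyN = 5, polySigma = 1.1) {
  stopifnot(pyrScale > 0, pyrScale < 1, levels >= 1, winsize >= 3,
            iters >= 1, polyN >= 2)
  structure(list(pyrScale = pyrScale, levels = as.integer(levels),
                 winsize = as.integer(winsize), iters = as.integer(iters),
                 polyN = as.integer(polyN), polySigma = polySigma),
            class = "FlowConfig")
}

#' Mask a frame
#'
#' Pixels outside the mask are set to zero; inside they are unchanged. Only
#' the pixels representing the fish survive, so the flow stage sees the
#' fish's displacement and nothing of the static apparatus.
#'
#' @param frame numeric matrix (or (h, w, c) array)
#' @param mask logical matrix from [buildMask()]
#' @return masked frame, same shape as the input
#' @export
applyMask <- function(frame, mask) {
  if (is.matrix(frame)) {
    if (!all(dim(frame) == dim(mask))) stop("frame/mask shape mismatch")
    return(frame * mask)
  }
  d <- dim(frame)
  if (length(d) != 3 || !all(d[1:2] == dim(mask)))
    stop("frame/mask shape mismatch")
  frame * as.vector(mask)
}

#' Dense optical flow between two frames
#'
#' Farneback polynomial-expansion flow: each frame is locally approximated
#' by quadratic polynomials under a Gaussian applicability, and the
#' displacement field is estimated from how the polynomial coefficients
#' transform between the two frames, refined iteratively over an image
#' pyramid. Positive `dx` points right (increasing column), positive `dy`
#' down (increasing row), in pixels/frame.
#'
#' @param frameA,frameB numeric matrices of identical shape, consecutive in
#'   time (flow is A -> B)
#' @param config a [flowConfig()]
#' @param mask optional logical matrix restricting the field's support:
#'   displacements outside it are set to zero. When the inputs are masked
#'   frames, passing the union of the two fish masks enforces the contract
#'   that flow is zero outside the masked region.
#' @return object of class `FlowField`: list with matrices `dx`, `dy`
#' @export
denseFlow <- function(frameA, frameB, config = flowConfig(), mask = NULL) {
  frameA <- asGray(frameA); frameB <- asGray(frameB)
  if (!all(dim(frameA) == dim(frameB))) stop("frame shape mismatch")
  res <- cppFarneback(frameA, frameB, config$pyrScale, config$levels,
                      config$winsize, config$iters, config$polyN,
                      config$polySigma)
  dx <- res$dx; dy <- res$dy
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(dx))) stop("mask shape mismatch")
    dx[!mask] <- 0
    dy[!mask] <- 0
  }
  structure(list(dx = dx, dy = dy), class = "FlowField")
}

#' Render a flow field as a color image
#'
#' Conventional flow visualization: direction maps to hue, magnitude to
#' value (full saturation), with magnitudes normalized by `magCap` and
#' clipped at 1. Zero flow is black, so static regions stay dark in the
#' fused trajectory image.
#'
#' @param flow a `FlowField` (list with `dx`, `dy`)
#' @param magCap magnitude (pixels/frame) mapped to full brightness
#' @return numeric (h, w, 3) array in [0, 1]
#' @export
flowToImage <- function(flow, magCap = 10) {
  dx <- flow$dx; dy <- flow$dy
  stopifnot(all(is.finite(dx)), all(is.finite(dy)))
  mag <- sqrt(dx^2 + dy^2)
  hue <- (atan2(dy, dx) + pi) / (2 * pi)
  val <- pmin(mag / magCap, 1)
  rgb <- hsv2rgbNum(as.vector(hue), 1, as.vector(val))
  array(c(rgb$r, rgb$g, rgb$b), dim = c(nrow(dx), ncol(dx), 3))
}

#' Fuse flow images into one trajectory image
#'
#' Per-pixel, per-channel maximum over the ordered flow images, then a
#' bilinear resize to 256x256. The max operator preserves faint early
#' motion against later motion and is idempotent; a sum-then-normalize
#' fusion is available via `method = "sum"`.
#'
#' @param flowImages nonempty list of (h, w, 3) arrays in [0, 1]
#' @param method `"max"` (default) or `"sum"` (normalized by its maximum)
#' @param size output side length (default 256)
#' @return numeric (size, size, 3) array in [0, 1]
#' @export
fuseTrajectory <- function(flowImages, method = c("max", "sum"),
                          size = 256L) {
  method <- match.arg(method)
  if (!length(flowImages)) stop("need at least one flow image")
  d <- dim(flowImages[[1]])
  if (any(!vapply(flowImages, function(x) all(dim(x) == d), logical(1))))
    stop("flow images must share one shape")
  fused <- if (method == "max") Reduce(pmax, flowImages)
  else {
    s <- Reduce(`+`, flowImages)
    if (max(s) > 0) s / max(s) else s
  }
  clamp01(resizeImage(fused, size, size))
}

#' Trajectory image of a whole clip
#'
#' The composition the tracking stage performs per clip: per-frame circular
#' masks from the detections, masked frames, dense flow between the t-1
#' consecutive masked pairs, flow visualization, and fusion into a single
#' 256x256x3 trajectory image. Frames without a detection contribute an
#' empty mask, hence a black flow frame — noise the pipeline tolerates, not
#' an error.
#'
#' For speed, flow is computed on a window around the union of the two
#' masks (the masked frames are identically zero elsewhere, where the flow
#' is zero by construction); `crop = FALSE` forces full-frame computation.
#'
#' @param clip a [VideoClip-class] (>= 2 frames)
#' @param detections data.frame from [detectClip()]; per frame the highest
#'   confidence detection is used
#' @param config a [flowConfig()]
#' @param radius mask radius in pixels
#' @param magCap magnitude cap for [flowToImage()]
#' @param method fusion operator for [fuseTrajectory()]
#' @param crop compute flow on a padded window around the masks
#' @return 256x256x3 trajectory image
#' @export
clipToTrajectory <- function(clip, detections, config = flowConfig(),
                             radius = 10, magCap = 10,
                             method = c("max", "sum"), crop = TRUE) {
  method <- match.arg(method)
  t <- nFrames(clip)
  if (t < 2) stop("clip must contain at least 2 frames")
  shape <- frameSize(clip)
  h <- shape[1]; w <- shape[2]
  best <- vector("list", t)
  if (nrow(detections)) {
    for (k in seq_len(t)) {
      rows <- detections[detections$frame == k, , drop = FALSE]
      if (nrow(rows))
        best[[k]] <- rows[which.max(rows$confidence), , drop = FALSE]
    }
  }
  masks <- lapply(best, function(b) buildMask(shape, b, radius))
  masked <- lapply(seq_len(t), function(k)
    applyMask(clip@frames[, , k], masks[[k]]))
  pad <- config$winsize + config$polyN
  if (!crop) {
    flowImages <- lapply(seq_len(t - 1), function(k) {
      if (!any(masks[[k]]) && !any(masks[[k + 1]]))
        return(array(0, dim = c(h, w, 3)))
      flowToImage(denseFlow(masked[[k]], masked[[k + 1]], config,
                            mask = masks[[k]] | masks[[k + 1]]), magCap)
    })
    return(fuseTrajectory(flowImages, method = method))
  }
  # fuse incrementally: each pair only touches its padded mask window,
  # the rest of the flow image is identically black
  fused <- array(0, dim = c(h, w, 3))
  total <- array(0, dim = c(h, w, 3))
  for (k in seq_len(t - 1)) {
    m1 <- masks[[k]]; m2 <- masks[[k + 1]]
    if (!any(m1) && !any(m2)) next
    idx <- which(m1 | m2)
    rows <- range(((idx - 1L) %% h) + 1L)
    cols <- range(((idx - 1L) %/% h) + 1L)
    r0 <- max(1, rows[1] - pad); r1 <- min(h, rows[2] + pad)
    c0 <- max(1, cols[1] - pad); c1 <- min(w, cols[2] + pad)
    fl <- denseFlow(masked[[k]][r0:r1, c0:c1],
                    masked[[k + 1]][r0:r1, c0:c1], config,
                    mask = (m1 | m2)[r0:r1, c0:c1])
    img <- flowToImage(fl, magCap)
    if (method == "max") {
      fused[r0:r1, c0:c1, ] <- pmax(fused[r0:r1, c0:c1, , drop = FALSE],
                                    img)
    } else {
      total[r0:r1, c0:c1, ] <- total[r0:r1, c0:c1, , drop = FALSE] + img
    }
  }
  if (method == "sum") {
    fused <- if (max(total) > 0) total / max(total) else total
  }
  clamp01(resizeImage(fused, 256L, 256L))
}

#' Circular hue histogram of a trajectory image
#'
#' Value-weighted histogram of hue over sufficiently bright pixels; a
#' no-change clip (one swim direction) concentrates its mass in one hue
#' family, while a direction-reversal clip adds the opposed hue family.
#' Used as a diagnostic and in tests for motion-direction content.
#'
#' @param img (h, w, 3) trajectory image
#' @param nbins number of hue bins
#' @param vmin minimum brightness (max channel value) for a pixel to count
#' @return numeric vector of `nbins` masses summing to 1 (all-dark images
#'   return all zeros)
#' @export
trajectoryHueHistogram <- function(img, nbins = 36, vmin = 0.05) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  v <- pmax(r, pmax(g, b))
  sel <- v > vmin
  if (!any(sel)) return(numeric(nbins))
  hsv <- rgb2hsv(rbind(as.vector(r[sel]), as.vector(g[sel]),
                       as.vector(b[sel])), maxColorValue = 1)
  bins <- pmin(floor(hsv[1, ] * nbins) + 1, nbins)
  wts <- hsv[3, ]
  out <- vapply(seq_len(nbins), function(i) sum(wts[bins == i]), numeric(1))
  out / sum(out)
}
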