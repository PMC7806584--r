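# Internal helpers shared across modules.

# Run `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647) + 1L
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# Vectorized HSV -> RGB on numeric vectors in [0,1]; h wraps.
hsv2rgbNum <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  n <- length(h)
  r <- numeric(n); g <- numeric(n); b <- numeric(n)
  pick <- list(c("v", "t", "p"), c("q", "v", "p"), c("p", "v", "t"),
               c("p", "q", "v"), c("t", "p", "v"), c("v", "p", "q"))
  env <- list(v = v, t = t, p = p, q = q)
  for (ii in 0:5) {
    sel <- i == ii
    if (!any(sel)) next
    ch <- pick[[ii + 1]]
    r[sel] <- env[[ch[1]]][sel]
    g[sel] <- env[[ch[2]]][sel]
    b[sel] <- env[[ch[3]]][sel]
  }
  list(r = r, g = g, b = b)
}

# Bilinear resize of a (h, w) matrix or (h, w, c) array via EBImage.
# EBImage stores images as (x, y[, c]), ours are (row=y, col=x[, c]).
resizeImage <- function(img, height, width) {
  if (is.matrix(img)) {
    if (nrow(img) == height && ncol(img) == width) return(img)
    out <- EBImage::resize(t(img), w = width, h = height)
    return(t(as.matrix(out)))
  }
  stopifnot(length(dim(img)) == 3)
  if (dim(img)[1] == height && dim(img)[2] == width) return(img)
  x <- aperm(img, c(2, 1, 3))
  out <- EBImage::resize(EBImage::Image(x, colormode = "Color"),
                         w = width, h = height)
  aperm(as.array(out), c(2, 1, 3))
}

# Collapse a (h, w, 3) array to grayscale; pass matrices through.
asGray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3) return(rowMeans(frame, dims = 2))
  stop("frame must be a matrix or an (h, w, c) array")
}
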