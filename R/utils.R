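# Internal helpers shared across modules.

# Evaluate a body with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Piecewise-linear border interpolation at arbitrary x, constant beyond the
# first/last vertex. A single-vertex border is a horizontal line.
.interpBorder <- function(border, x) {
  if (nrow(border) == 1L) return(rep(border[1, 2], length(x)))
  o <- order(border[, 1])
  stats::approx(border[o, 1], border[o, 2], xout = x, rule = 2,
                ties = "ordered")$y
}

# Centered moving average with shrinking windows at the edges. For an even
# window the covered span is [i - (w/2 - 1), i + w/2].
.movingAverageShrink <- function(x, window) {
  n <- length(x)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Mean over a disk neighborhood (zero-padded), used for the capillary-bed
# perfusion field of the contrast renderer.
.diskMean <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2L * r, W + 2L * r)
  xp[r + 1:H, r + 1:W] <- x
  acc <- matrix(0, H, W)
  n <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    if (dy * dy + dx * dx <= r * r) {
      acc <- acc + xp[(r + dy) + 1:H, (r + dx) + 1:W]
      n <- n + 1L
    }
  }
  acc / n
}

# Centered running median with symmetric shrinking windows (always an odd
# sample count), NA-tolerant.
.runningMedian <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(i - 1L, n - i, half)
    w <- x[(i - h):(i + h)]
    w <- w[is.finite(w)]
    if (!length(w)) NA_real_ else stats::median(w)
  }, numeric(1))
}
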