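#' @include AllClasses.R
NULL

#' Smooth a time-intensity curve with a simple moving average
#'
#' Centered 32-sample moving average used for noise reduction of per-pixel
#' microbubble time-intensity curves. Output length equals input length;
#' near the edges the window shrinks (for the even default the covered span
#' is \code{[i - 15, i + 16]}, clipped to the series).
#'
#' @param series numeric intensity series (one pixel over frames).
#' @param window filter length in samples.
#' @return smoothed series of the same length.
#' @export
smoothTic <- function(series, window = 32) {
  if (window < 1) stop("window must be >= 1")
  if (length(series) < window)
    stop("series shorter than the smoothing window")
  .movingAverageShrink(series, as.integer(window))
}

# Fast core: returns c(k, peakTime, peakValue, ok, rss).
.fitDecayCore <- function(series, fps, maxIntensityThreshold,
                          latestPeakTime, minPostPeak, refine) {
  n <- length(series)
  t <- (seq_len(n) - 1) / fps
  pk <- which.max(series)
  peakValue <- series[pk]
  peakTime <- t[pk]
  fail <- c(0, peakTime, peakValue, 0, NA_real_)
  if (peakValue < maxIntensityThreshold) return(fail)
  if (peakTime >= latestPeakTime) return(fail)
  post <- pk:n
  y <- series[post]
  tp <- t[post]
  pos <- y > 0                       # log undefined at or below 0
  if (sum(pos) < minPostPeak) return(fail)
  ty <- tp[pos] - peakTime
  ly <- log(y[pos])
  # weights y^2: var(log y) ~ sigma^2 / y^2 under additive noise, so this
  # is the standard linearization weighting and is exact on clean decays
  w <- y[pos]^2
  sw <- sum(w)
  mx <- sum(w * ty) / sw; my <- sum(w * ly) / sw
  slope <- sum(w * (ty - mx) * (ly - my)) / sum(w * (ty - mx)^2)
  k <- max(0, -slope)
  A <- exp(my - slope * mx)
  if (refine) {
    fit <- tryCatch(
      stats::nls(yy ~ A0 * exp(-k0 * tt),
                 data = list(yy = y[pos], tt = ty),
                 start = list(A0 = A, k0 = max(k, 1e-6)),
                 algorithm = "port", lower = c(0, 0)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      A <- cf[["A0"]]; k <- cf[["k0"]]
    }
  }
  rss <- sum((y - A * exp(-k * (tp - peakTime)))^2)
  c(k, peakTime, peakValue, 1, rss)
}

#' Fit a first-order exponential washout to a time-intensity curve
#'
#' Starting from the time of maximum (smoothed) intensity, fits
#' \code{y(t) = A exp(-k (t - tPeak))} to the post-peak segment by linear
#' least squares on \code{log y} (samples at or below 0 are excluded), with
#' an optional nonlinear refinement. The magnitude of the decay constant
#' \code{k} is the flow surrogate (1/s): faster washout, greater perfusion.
#'
#' Pixels that never received microbubble signal are assigned 0 1/s rather
#' than fit: those whose maximum intensity stays below
#' \code{maxIntensityThreshold} (0.015 AU) or whose peak occurs at or after
#' \code{latestPeakTime} (75 s) into the recording, as well as curves with
#' fewer than \code{minPostPeak} usable post-peak samples.
#'
#' @param series smoothed intensity series (see \code{\link{smoothTic}}).
#' @param fps frames per second of the recording.
#' @param maxIntensityThreshold minimum peak intensity, AU.
#' @param latestPeakTime latest admissible peak time, s (boundary
#'   inclusive: a peak at exactly 75 s disqualifies).
#' @param minPostPeak minimum number of positive post-peak samples.
#' @param refine if \code{TRUE}, refine the log-linear estimate with a
#'   nonlinear least-squares pass on the intensity scale.
#' @return a \linkS4class{DecayFitResult}.
#' @export
fitDecay <- function(series, fps, maxIntensityThreshold = 0.015,
                     latestPeakTime = 75, minPostPeak = 10,
                     refine = FALSE) {
  if (fps <= 0) stop("fps must be positive")
  r <- .fitDecayCore(series, fps, maxIntensityThreshold, latestPeakTime,
                     minPostPeak, refine)
  new("DecayFitResult", decayConstant = r[1], peakTime = r[2],
      peakValue = r[3], fitOk = r[4] == 1, rss = r[5])
}

#' Build a decay-constant perfusion map from a contrast recording
#'
#' Applies the full per-pixel pipeline of the contrast arm: moving-average
#' smoothing of each time-intensity curve, exponential washout fit from the
#' intensity peak, and the zero-assignment rules for unperfused pixels. The
#' rules are exhaustive: every pixel is either fit or explicitly zeroed;
#' the output contains no NaN.
#'
#' @param stack a contrast \linkS4class{FrameStack}.
#' @param window smoothing window, samples.
#' @param maxIntensityThreshold,latestPeakTime,minPostPeak,refine passed to
#'   \code{\link{fitDecay}}.
#' @return a \linkS4class{FlowMap} in 1/s; \code{validMask} marks pixels
#'   with a successful fit.
#' @export
decayMap <- function(stack, window = 32, maxIntensityThreshold = 0.015,
                     latestPeakTime = 75, minPostPeak = 10,
                     refine = FALSE) {
  stopifnot(is(stack, "FrameStack"))
  if (stack@modality != "contrast")
    stop("decayMap requires a contrast stack")
  d <- dim(stack@data)
  if (d[3] < window) stop("recording shorter than the smoothing window")
  m <- matrix(stack@data, d[1] * d[2], d[3])
  peak <- do.call(pmax, lapply(seq_len(d[3]), function(j) m[, j]))
  kvals <- numeric(d[1] * d[2])
  ok <- logical(d[1] * d[2])
  candidates <- which(peak >= maxIntensityThreshold)
  for (p in candidates) {
    s <- .movingAverageShrink(m[p, ], as.integer(window))
    r <- .fitDecayCore(s, stack@fps, maxIntensityThreshold,
                       latestPeakTime, minPostPeak, refine)
    if (r[4] == 1) {
      kvals[p] <- r[1]
      ok[p] <- TRUE
    }
  }
  new("FlowMap", values = matrix(kvals, d[1], d[2]), units = "1/s",
      validMask = matrix(ok, d[1], d[2]), pixelSize = stack@pixelSize)
}

#' Grayscale opening with a non-flat offset-disk structuring element
#'
#' Erosion followed by dilation with the non-flat (offset disk) structuring
#' element \code{b(s) = height * sqrt(1 - |s|^2 / r^2)} on the disk
#' \code{|s| <= r}. The opening is anti-extensive (output <= input) and
#' idempotent, and suppresses isolated bright speckle narrower than the
#' disk — the microbubble-aggregate artifact in decay maps. Image borders
#' are handled by symmetric reflection.
#'
#' @param x numeric matrix (e.g. a decay map's values).
#' @param radiusPx disk radius, px (>= 1).
#' @param height element height, in the image's units (1/s for decay maps).
#' @return matrix of the same shape.
#' @export
openOffsetDisk <- function(x, radiusPx = 5, height = 0.05) {
  if (!is.matrix(x)) stop("x must be a matrix")
  r <- as.integer(radiusPx)
  if (r < 1L) stop("radius must be >= 1")
  if (height < 0) stop("height must be >= 0")
  if (r > min(dim(x)) / 2) stop("radius larger than image half-size")
  off <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- off$dy^2 + off$dx^2 <= r^2
  off <- off[keep, ]
  b <- height * sqrt(1 - (off$dy^2 + off$dx^2) / r^2)
  ero <- .morphPass(x, off, b, r, erode = TRUE)
  .morphPass(ero, off, b, r, erode = FALSE)
}

# One erosion or dilation pass over a reflect-padded image.
.morphPass <- function(x, off, b, r, erode) {
  H <- nrow(x); W <- ncol(x)
  ridx <- c(r:1, 1:H, H:(H - r + 1))
  cidx <- c(r:1, 1:W, W:(W - r + 1))
  xp <- x[ridx, cidx, drop = FALSE]
  acc <- NULL
  for (i in seq_len(nrow(off))) {
    rows <- (r + off$dy[i]) + 1:H
    cols <- (r + off$dx[i]) + 1:W
    v <- if (erode) xp[rows, cols, drop = FALSE] - b[i]
         else xp[rows, cols, drop = FALSE] + b[i]
    acc <- if (is.null(acc)) v
           else if (erode) pmin(acc, v) else pmax(acc, v)
  }
  acc
}

#' Full contrast-arm map with speckle removal
#'
#' \code{\link{decayMap}} followed by \code{\link{openOffsetDisk}}; the
#' published contrast pipeline end to end.
#'
#' @param stack a contrast \linkS4class{FrameStack}.
#' @param radiusPx,height structuring element, px and 1/s.
#' @param ... passed to \code{\link{decayMap}}.
#' @return a \linkS4class{FlowMap} in 1/s.
#' @export
contrastFlowMap <- function(stack, radiusPx = 5, height = 0.05, ...) {
  m <- decayMap(stack, ...)
  opened <- openOffsetDisk(m@values, radiusPx, height)
  opened[opened < 0] <- 0
  mask <- m@validMask & opened > 0
  opened[!mask] <- 0
  new("FlowMap", values = opened, units = "1/s", validMask = mask,
      pixelSize = m@pixelSize)
}
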