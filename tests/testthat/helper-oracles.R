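# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (double loops, definitional formulas)
# and share no code with the implementation.

flowMapOf <- function(values, units = "AU", pixelSize = 0.05,
                      validMask = NULL) {
  if (is.null(validMask)) validMask <- matrix(TRUE, nrow(values), ncol(values))
  new("FlowMap", values = values, units = units, validMask = validMask,
      pixelSize = pixelSize)
}

profileOf <- function(centers, values, counts = NULL, bw = NULL,
                      units = "AU") {
  if (is.null(bw)) bw <- if (length(centers) > 1) centers[2] - centers[1] else 0.1
  if (is.null(counts)) counts <- rep(100L, length(centers))
  new("SpatialProfile", binCenters = centers, indexValues = values,
      binCounts = as.integer(counts), binWidth = bw, units = units)
}

verticalGeometry <- function(x0, H, W, pixelSize = 0.05,
                             upperRow = 10, lowerRow = H - 10) {
  new("InjuryGeometry",
      injuryLine = rbind(c(x0, 2), c(x0, H - 1)),
      upperBorder = cbind(c(1, W), c(upperRow, upperRow)),
      lowerBorder = cbind(c(1, W), c(lowerRow, lowerRow)),
      pixelSize = pixelSize)
}

stackOf <- function(data, fps = 39, pixelSize = 0.05,
                    modality = "noncontrast") {
  new("FrameStack", data = data, fps = fps, pixelSize = pixelSize,
      modality = modality)
}

# Grayscale opening with the offset-disk element, direct double loops over
# every pixel and every structuring-element offset, reflect padding.
bruteOpenOffsetDisk <- function(x, r, h) {
  H <- nrow(x); W <- ncol(x)
  ridx <- c(r:1, 1:H, H:(H - r + 1))
  cidx <- c(r:1, 1:W, W:(W - r + 1))
  pad <- function(m) m[ridx, cidx]
  pass <- function(m, erode) {
    mp <- pad(m)
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      best <- if (erode) Inf else -Inf
      for (dy in -r:r) for (dx in -r:r) {
        if (dy^2 + dx^2 <= r^2) {
          b <- h * sqrt(1 - (dy^2 + dx^2) / r^2)
          v <- if (erode) mp[r + i + dy, r + j + dx] - b
               else mp[r + i + dy, r + j + dx] + b
          best <- if (erode) min(best, v) else max(best, v)
        }
      }
      out[i, j] <- best
    }
    out
  }
  pass(pass(x, TRUE), FALSE)
}

# Minimum distance from a point to a segment, definitional.
brutePointSegDist <- function(px, py, a, b) {
  besti <- Inf
  for (tt in seq(0, 1, length.out = 20001)) {
    qx <- a[1] + tt * (b[1] - a[1])
    qy <- a[2] + tt * (b[2] - a[2])
    besti <- min(besti, sqrt((px - qx)^2 + (py - qy)^2))
  }
  besti
}

# Topographic prominence of every strict local maximum (no-ties signals):
# walk out from the peak to the nearest higher sample (or the end) on each
# side and take the higher of the two interval minima.
brutePeaks <- function(y) {
  n <- length(y)
  out <- list()
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) {
      l <- i
      while (l > 1 && y[l] <= y[i]) l <- l - 1
      leftMin <- min(y[l:i])
      r <- i
      while (r < n && y[r] <= y[i]) r <- r + 1
      rightMin <- min(y[i:r])
      out[[length(out) + 1]] <- c(idx = i, prom = y[i] - max(leftMin, rightMin))
    }
  }
  if (!length(out)) return(data.frame(idx = integer(), prom = numeric()))
  as.data.frame(do.call(rbind, out))
}

# Definitional Spearman: rank with average ties, then Pearson on the ranks.
bruteSpearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

naiveMovingAverage <- function(x, window) {
  n <- length(x)
  left <- (window - 1) %/% 2
  right <- window - 1 - left
  sapply(seq_len(n), function(i) mean(x[max(1, i - left):min(n, i + right)]))
}

naiveRunningMedian <- function(x, half) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    h <- min(i - 1, n - i, half)
    w <- sort(x[(i - h):(i + h)])
    m <- length(w)
    if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  })
}
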