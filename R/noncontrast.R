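#' @include AllClasses.R
NULL

#' Decode an RGB color-Doppler frame into a velocity-index map
#'
#' Nearest-neighbor lookup against a color-to-velocity-index table: each
#' pixel takes the index of the closest LUT color (Euclidean distance in RGB
#' space). Pixels farther than \code{maxColorDistance} from every LUT entry
#' (grayscale B-mode background, annotation overlays) map to 0. Grayscale
#' recordings that already carry index values bypass this decode.
#'
#' @param rgbFrame numeric \code{H x W x 3} array, channels in [0, 1].
#' @param lut data frame or matrix with columns \code{r, g, b, index}:
#'   colors in [0, 1], indices in [0, 1] strictly ascending, colors unique.
#' @param maxColorDistance reject radius in RGB space.
#' @return \code{H x W} numeric velocity-index map.
#' @seealso \code{\link{defaultHotLut}}
#' @export
colorToVelocityIndex <- function(rgbFrame, lut, maxColorDistance = 0.2) {
  d <- dim(rgbFrame)
  if (length(d) != 3L || d[3] != 3L)
    stop("rgbFrame must be an H x W x 3 array")
  lut <- as.matrix(lut)
  if (nrow(lut) < 1L || ncol(lut) < 4L)
    stop("LUT must have columns r, g, b, index")
  cols <- lut[, 1:3, drop = FALSE]
  idx <- lut[, 4]
  if (any(idx < 0 | idx > 1)) stop("LUT indices must lie in [0, 1]")
  if (nrow(lut) > 1L && any(diff(idx) <= 0))
    stop("LUT indices must be strictly ascending")
  if (anyDuplicated(cols)) stop("LUT colors must be unique")
  n <- d[1] * d[2]
  pix <- matrix(rgbFrame, n, 3L)
  best <- rep.int(1L, n)
  bestD <- rowSums((pix - matrix(cols[1, ], n, 3L, byrow = TRUE))^2)
  for (k in seq_len(nrow(cols))[-1]) {
    dk <- rowSums((pix - matrix(cols[k, ], n, 3L, byrow = TRUE))^2)
    upd <- dk < bestD
    best[upd] <- k
    bestD[upd] <- dk[upd]
  }
  out <- idx[best]
  out[sqrt(bestD) > maxColorDistance] <- 0
  matrix(out, d[1], d[2])
}

#' A linear hot-scale color-to-velocity-index table
#'
#' Documented default LUT for scanners whose exact colormap is unknown: a
#' red-to-yellow-to-white ramp (far from grayscale B-mode background) with
#' equally spaced indices ascending to 1.
#'
#' @param n number of entries.
#' @return data frame with columns \code{r, g, b, index}.
#' @export
defaultHotLut <- function(n = 16) {
  tt <- seq(1 / 3, 1, length.out = n)
  data.frame(r = 1,
             g = pmin(1, pmax(0, 3 * tt - 1)),
             b = pmin(1, pmax(0, 3 * tt - 2)),
             index = seq_len(n) / n)
}

#' Time-average a recording into a flow map
#'
#' Per-pixel arithmetic mean across frames: each 5-s velocity-index
#' recording collapses to a single image. Units follow the modality
#' (velocity index AU for non-contrast input).
#'
#' @param stack a \linkS4class{FrameStack}.
#' @return a \linkS4class{FlowMap}.
#' @export
timeAverageMap <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@data)
  if (d[3] < 1L) stop("empty stack")
  m <- matrix(rowMeans(matrix(stack@data, d[1] * d[2], d[3])), d[1], d[2])
  new("FlowMap", values = m, units = "AU",
      validMask = matrix(TRUE, d[1], d[2]),
      pixelSize = stack@pixelSize)
}
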