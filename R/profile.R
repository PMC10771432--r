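#' @include AllClasses.R
NULL

#' Signed distance from every pixel to the injury line
#'
#' Computes, for each pixel center, the minimum Euclidean distance to the
#' injury line segment, scaled to mm, and signs it by side: pixels on the
#' rostral side (image left by default) are negative, caudal positive.
#'
#' @param geometry an \linkS4class{InjuryGeometry}.
#' @param dim image dimensions \code{c(H, W)} (rows, columns).
#' @param rostralRight set \code{TRUE} if the head is to the image right;
#'   flips the sign convention.
#' @return \code{H x W} numeric matrix of signed distances in mm.
#' @details The injury line is drawn transverse to the cord's long
#'   (horizontal) axis; a line parallel to that axis leaves left/right
#'   undefined and is rejected.
#' @export
signedDistanceMap <- function(geometry, dim, rostralRight = FALSE) {
  stopifnot(is(geometry, "InjuryGeometry"), length(dim) == 2L)
  p1 <- geometry@injuryLine[1, ]
  p2 <- geometry@injuryLine[2, ]
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 < .Machine$double.eps)
    stop("degenerate injury line (zero length)")
  if (abs(v[2]) < .Machine$double.eps^0.5)
    stop("injury line is parallel to the cord axis; cannot sign distances")
  H <- dim[1]; W <- dim[2]
  px <- matrix(seq_len(W), H, W, byrow = TRUE)
  py <- matrix(seq_len(H), H, W)
  dx <- px - p1[1]; dy <- py - p1[2]
  tt <- pmin(1, pmax(0, (dx * v[1] + dy * v[2]) / len2))
  ex <- dx - tt * v[1]; ey <- dy - tt * v[2]
  d <- sqrt(ex * ex + ey * ey) * geometry@pixelSize
  cross <- dx * v[2] - dy * v[1]
  # sign(cross) equals sign(-v[2]) for pixels left of the oriented line
  leftNeg <- sign(cross) * sign(-v[2])
  s <- -leftNeg
  if (rostralRight) s <- -s
  d * s
}

#' Region-of-interest mask between the cord borders
#'
#' Pixels strictly between the upper and lower border polylines (linear
#' interpolation between vertices, constant continuation beyond the end
#' vertices). Excludes the borders themselves, mirroring the manual tracing
#' that keeps the anterior/posterior spinal arteries out of the analysis.
#'
#' @param geometry an \linkS4class{InjuryGeometry}.
#' @param dim image dimensions \code{c(H, W)}.
#' @return \code{H x W} logical matrix.
#' @export
roiMask <- function(geometry, dim) {
  stopifnot(is(geometry, "InjuryGeometry"), length(dim) == 2L)
  H <- dim[1]; W <- dim[2]
  xs <- seq_len(W)
  up <- .interpBorder(geometry@upperBorder, xs)
  lo <- .interpBorder(geometry@lowerBorder, xs)
  rows <- matrix(seq_len(H), H, W)
  upm <- matrix(up, H, W, byrow = TRUE)
  lom <- matrix(lo, H, W, byrow = TRUE)
  rows > upm & rows < lom
}

#' Area-adjusted flow index of one distance bin
#'
#' The bin statistic \code{I = v * Apx / Aroi}: the mean brightness \code{v}
#' of the "colored" (flowing) pixels times the fraction of the bin's area
#' they occupy. A pixel is colored when its value exceeds
#' \code{coloredThreshold}. With the default threshold 0 this reduces
#' algebraically to the plain mean including zeros.
#'
#' @param values numeric vector of the bin's pixel values.
#' @param coloredThreshold threshold above which a pixel counts as colored.
#' @return the index \code{I}; \code{NA} for an empty bin.
#' @export
areaAdjustedIndex <- function(values, coloredThreshold = 0) {
  if (length(values) == 0L) return(NA_real_)
  colored <- values > coloredThreshold
  if (!any(colored)) return(0)
  mean(values[colored]) * mean(colored)
}

#' Bin a flow map into a spatial profile over distance from injury
#'
#' Pixels inside the region of interest are assigned to half-open distance
#' bins \code{[edge, edge + binWidth)} whose edges are anchored at 0 mm (so
#' "either side of 0" is well defined), and the area-adjusted index is
#' computed per bin. Interior bins with no pixels are kept as missing
#' (\code{NA}), never silently zero.
#'
#' @param flow a \linkS4class{FlowMap}.
#' @param distances signed distance matrix (mm) from
#'   \code{\link{signedDistanceMap}}.
#' @param mask logical ROI matrix from \code{\link{roiMask}}.
#' @param binWidth bin width in mm.
#' @param coloredThreshold passed to \code{\link{areaAdjustedIndex}}.
#' @return a \linkS4class{SpatialProfile}.
#' @export
binProfile <- function(flow, distances, mask, binWidth = 0.1,
                       coloredThreshold = 0) {
  stopifnot(is(flow, "FlowMap"), binWidth > 0)
  v <- flow@values
  if (!identical(dim(v), dim(distances)) || !identical(dim(v), dim(mask)))
    stop("flow, distances and mask shapes must agree")
  sel <- which(mask)
  if (length(sel) == 0L) stop("empty region of interest")
  d <- distances[sel]
  val <- v[sel]
  # half-open bins [edge, edge + width): nudge distances sitting exactly on
  # an edge (within fp error) into the upper bin so ties break one way
  idx <- floor(d / binWidth + 1e-7)
  rng <- range(idx)
  bins <- rng[1]:rng[2]
  grp <- match(idx, bins)
  counts <- tabulate(grp, nbins = length(bins))
  iv <- rep(NA_real_, length(bins))
  for (g in which(counts > 0L)) {
    iv[g] <- areaAdjustedIndex(val[grp == g], coloredThreshold)
  }
  new("SpatialProfile",
      binCenters = (bins + 0.5) * binWidth,
      indexValues = iv,
      binCounts = as.integer(counts),
      binWidth = binWidth,
      units = flow@units)
}

#' Smooth a spatial profile with a centered averaging filter
#'
#' Moving average of the given physical width. The width is converted to a
#' bin count and raised to the next odd number so the filter is centered
#' (1 mm over 0.1 mm bins uses 11 bins). Missing bins are excluded from each
#' local mean; a bin's smoothed value is defined whenever its window contains
#' at least one non-missing bin, so the support never grows by more than half
#' a window.
#'
#' @param profile a \linkS4class{SpatialProfile}.
#' @param window filter width in mm.
#' @return a smoothed \linkS4class{SpatialProfile} (pixel counts unchanged).
#' @export
smoothProfile <- function(profile, window = 1.0) {
  stopifnot(is(profile, "SpatialProfile"), window > 0)
  nb <- round(window / profile@binWidth)
  if (nb < 1L) nb <- 1L
  if (nb %% 2L == 0L) nb <- nb + 1L
  half <- (nb - 1L) %/% 2L
  y <- profile@indexValues
  n <- length(y)
  out <- vapply(seq_len(n), function(i) {
    w <- y[max(1L, i - half):min(n, i + half)]
    w <- w[is.finite(w)]
    if (!length(w)) NA_real_ else mean(w)
  }, numeric(1))
  initialize(profile, indexValues = out)
}

#' Full flow-map-to-profile pipeline
#'
#' Convenience wrapper: signed distance map, ROI mask, binning and the 1 mm
#' averaging filter in one call.
#'
#' @param flow a \linkS4class{FlowMap}.
#' @param geometry an \linkS4class{InjuryGeometry}.
#' @param binWidth bin width, mm.
#' @param smoothWindow averaging filter width, mm; \code{NULL} to skip.
#' @param coloredThreshold passed to \code{\link{areaAdjustedIndex}}.
#' @param rostralRight passed to \code{\link{signedDistanceMap}}.
#' @return a \linkS4class{SpatialProfile}.
#' @export
flowProfile <- function(flow, geometry, binWidth = 0.1, smoothWindow = 1.0,
                        coloredThreshold = 0, rostralRight = FALSE) {
  dims <- dim(flow@values)
  d <- signedDistanceMap(geometry, dims, rostralRight = rostralRight)
  m <- roiMask(geometry, dims)
  p <- binProfile(flow, d, m, binWidth = binWidth,
                  coloredThreshold = coloredThreshold)
  if (!is.null(smoothWindow)) p <- smoothProfile(p, smoothWindow)
  p
}
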