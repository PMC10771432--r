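#' @include AllClasses.R profile.R zones.R
NULL

#' Per-frame spatial profiles of a continuous recording
#'
#' Applies the binning pipeline to every frame of a non-contrast recording
#' with identical geometry and binning, instead of time-averaging first.
#' Per-frame failures are recorded as missing bins, not fatal.
#'
#' @param stack a non-contrast \linkS4class{FrameStack}.
#' @param geometry an \linkS4class{InjuryGeometry}.
#' @param binWidth,smoothWindow,coloredThreshold,rostralRight as in
#'   \code{\link{flowProfile}}.
#' @return list of \linkS4class{SpatialProfile}, one per frame.
#' @export
perFrameProfiles <- function(stack, geometry, binWidth = 0.1,
                             smoothWindow = 1.0, coloredThreshold = 0,
                             rostralRight = FALSE) {
  stopifnot(is(stack, "FrameStack"))
  if (stack@modality != "noncontrast")
    stop("per-frame tracking expects a non-contrast stack")
  d <- dim(stack@data)
  dmap <- signedDistanceMap(geometry, d[1:2], rostralRight = rostralRight)
  m <- roiMask(geometry, d[1:2])
  lapply(seq_len(d[3]), function(k) {
    fm <- new("FlowMap", values = stack@data[, , k], units = "AU",
              validMask = matrix(TRUE, d[1], d[2]),
              pixelSize = stack@pixelSize)
    p <- binProfile(fm, dmap, m, binWidth = binWidth,
                    coloredThreshold = coloredThreshold)
    if (!is.null(smoothWindow)) p <- smoothProfile(p, smoothWindow)
    p
  })
}

#' Median-filter a zone location trace
#'
#' Running median that removes the jump discontinuities occasionally
#' produced by per-frame zone labeling, which tissue cannot biologically
#' exhibit. The default order-40 filter uses the centered 41-tap window
#' \code{[i - 20, i + 20]} (odd tap count, so runs of up to
#' \code{window / 2} aberrant frames are removed exactly); windows shrink
#' symmetrically at the trace edges and \code{NA} frames are ignored.
#'
#' @param locations numeric trace (mm per frame); \code{NA} where labeling
#'   failed.
#' @param window filter size in frames.
#' @return filtered trace of the same length.
#' @export
medianFilterLocations <- function(locations, window = 40) {
  if (window < 1) stop("window must be >= 1")
  n <- length(locations)
  if (n < window)
    warning("trace shorter than the filter window; window shrunk")
  .runningMedian(locations, as.integer(window) %/% 2L)
}

#' Assemble zone flow traces at filtered locations
#'
#' Reads, for every frame, the profile value at the (median-filtered)
#' umbra and penumbra locations, and recomputes the distal means per frame
#' beyond the filtered penumbra locations. Locations falling outside a
#' frame's profile domain yield missing values for that frame.
#'
#' @param profiles list of per-frame \linkS4class{SpatialProfile}.
#' @param locations matrix \code{T x 3} with columns \code{umbra},
#'   \code{rostralPenumbra}, \code{caudalPenumbra} (mm), typically filtered.
#' @param times frame times, s.
#' @param locationRaw optional unfiltered \code{T x 3} matrix, stored for QC.
#' @param filterWindow stored filter size, frames.
#' @return a \linkS4class{ZoneTimeSeries}.
#' @export
zoneTraces <- function(profiles, locations, times,
                       locationRaw = locations, filterWindow = 40) {
  n <- length(profiles)
  stopifnot(nrow(locations) == n, length(times) == n)
  flow <- matrix(NA_real_, n, 5,
                 dimnames = list(NULL, c("umbra", "rostralPenumbra",
                                         "caudalPenumbra", "rostralDistal",
                                         "caudalDistal")))
  ok <- logical(n)
  for (k in seq_len(n)) {
    p <- profiles[[k]]
    loc <- locations[k, ]
    if (any(!is.finite(loc))) next
    at <- function(l) {
      i <- which.min(abs(p@binCenters - l))
      if (abs(p@binCenters[i] - l) > p@binWidth / 2 + 1e-9) return(NA_real_)
      p@indexValues[i]
    }
    flow[k, "umbra"] <- at(loc[1])
    flow[k, "rostralPenumbra"] <- at(loc[2])
    flow[k, "caudalPenumbra"] <- at(loc[3])
    dd <- distalFlows(p, c(rostral = unname(loc[2]),
                           caudal = unname(loc[3])))
    flow[k, "rostralDistal"] <- dd["rostral"]
    flow[k, "caudalDistal"] <- dd["caudal"]
    ok[k] <- all(is.finite(flow[k, 1:3]))
  }
  colnames(locations) <- colnames(locationRaw) <-
    c("umbra", "rostralPenumbra", "caudalPenumbra")
  new("ZoneTimeSeries", times = times, locationRaw = locationRaw,
      locationFiltered = locations, flow = flow, labelingOk = ok,
      filterWindow = filterWindow)
}

#' Frame-by-frame zone tracking of a continuous recording
#'
#' The temporal pipeline: per-frame profiles, per-frame zone labeling, a
#' running-median filter on the umbra and penumbra location traces, then
#' flows sampled at the filtered locations (distal means recomputed per
#' frame beyond the filtered penumbras).
#'
#' @param stack a non-contrast \linkS4class{FrameStack}.
#' @param geometry an \linkS4class{InjuryGeometry}.
#' @param minProminence peak prominence threshold for per-frame labeling.
#' @param filterWindow median filter size, frames.
#' @param binWidth,smoothWindow,coloredThreshold,rostralRight as in
#'   \code{\link{flowProfile}}.
#' @return a \linkS4class{ZoneTimeSeries}.
#' @export
trackZones <- function(stack, geometry, minProminence = 0.03,
                       filterWindow = 40, binWidth = 0.1,
                       smoothWindow = 1.0, coloredThreshold = 0,
                       rostralRight = FALSE) {
  profiles <- perFrameProfiles(stack, geometry, binWidth = binWidth,
                               smoothWindow = smoothWindow,
                               coloredThreshold = coloredThreshold,
                               rostralRight = rostralRight)
  n <- length(profiles)
  raw <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    zl <- labelZones(profiles[[k]], minProminence)
    if (is.finite(zl@umbraLocation)) {
      raw[k, ] <- c(zl@umbraLocation, zl@penumbraLocation["rostral"],
                    zl@penumbraLocation["caudal"])
    }
  }
  filt <- apply(raw, 2, medianFilterLocations, window = filterWindow)
  if (n == 1L) filt <- matrix(filt, 1L, 3L)
  times <- (seq_len(n) - 1) / stack@fps
  zoneTraces(profiles, filt, times, locationRaw = raw,
             filterWindow = filterWindow)
}
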