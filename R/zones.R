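#' @include AllClasses.R
NULL

# Local maxima with topographic prominence (findpeaks semantics): a peak is
# a sample strictly greater than its neighbors; for a flat run higher than
# both flanking runs, the first sample of the run is reported. Prominence is
# peak height minus the higher of the two minima reached before the signal
# re-attains the peak height (or the signal end) on each side.
.peaksWithProminence <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks)) return(structure(integer(0), prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    l <- p
    while (l > 1L && y[l - 1L] < h) l <- l - 1L
    if (l > 1L) l <- l - 1L              # include the equal/higher sample
    leftMin <- min(y[l:p])
    r <- p
    while (r < n && y[r + 1L] < h) r <- r + 1L
    if (r < n) r <- r + 1L
    rightMin <- min(y[p:r])
    h - max(leftMin, rightMin)
  }, numeric(1))
  structure(peaks, prominence = prom)
}

#' Find the rostral and caudal penumbra peaks
#'
#' Detects local maxima of the spatial profile with topographic prominence
#' at least \code{minProminence} (default 0.03 AU) and selects, on each side
#' of 0 mm, the qualifying peak closest to the injury line. Failure on
#' either side is encoded in \code{labelingOk}, not an error.
#'
#' @param profile a \linkS4class{SpatialProfile} with bins on both sides of
#'   0 mm.
#' @param minProminence minimum topographic prominence.
#' @return list with \code{rostral} and \code{caudal}
#'   (\code{c(location=, flow=, prominence=)} or \code{NULL}), \code{peaks}
#'   (data frame of all qualifying peaks) and \code{labelingOk}.
#' @export
findPenumbraPeaks <- function(profile, minProminence = 0.03) {
  stopifnot(is(profile, "SpatialProfile"))
  keep <- is.finite(profile@indexValues)
  x <- profile@binCenters[keep]
  y <- profile@indexValues[keep]
  if (!any(x < 0) || !any(x > 0))
    stop("profile must have bins on both sides of 0 mm")
  pk <- .peaksWithProminence(y)
  prom <- attr(pk, "prominence")
  qual <- which(prom >= minProminence)
  peaks <- data.frame(location = x[pk[qual]], height = y[pk[qual]],
                      prominence = prom[qual])
  pick <- function(side) {
    cand <- if (side == "rostral") peaks[peaks$location < 0, , drop = FALSE]
            else peaks[peaks$location > 0, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    i <- which.min(abs(cand$location))
    c(location = cand$location[i], flow = cand$height[i],
      prominence = cand$prominence[i])
  }
  ros <- pick("rostral")
  cau <- pick("caudal")
  list(rostral = ros, caudal = cau, peaks = peaks,
       labelingOk = !is.null(ros) && !is.null(cau))
}

#' Locate the umbra between the two penumbra peaks
#'
#' The injury epicenter is the bin of minimum flow strictly between the
#' rostral and caudal penumbras. A minimum attained over consecutive bins
#' is reported at the center of the tied bins; non-consecutive ties are
#' broken toward 0 mm. A strictly monotone segment (degenerate) returns the
#' endpoint minimum with a note.
#'
#' @param profile a \linkS4class{SpatialProfile}.
#' @param rostralPeak,caudalPeak peak locations in mm (e.g. from
#'   \code{\link{findPenumbraPeaks}}).
#' @return list with \code{location} (mm), \code{flow}, and \code{note}.
#' @export
locateUmbra <- function(profile, rostralPeak, caudalPeak) {
  stopifnot(is(profile, "SpatialProfile"), rostralPeak < caudalPeak)
  keep <- is.finite(profile@indexValues)
  x <- profile@binCenters[keep]
  y <- profile@indexValues[keep]
  sel <- x > rostralPeak & x < caudalPeak
  if (!any(sel)) stop("no bins strictly between the peaks")
  xs <- x[sel]; ys <- y[sel]
  mn <- min(ys)
  tied <- which(ys == mn)
  note <- character(0)
  if (length(tied) == 1L) {
    loc <- xs[tied]
  } else {
    runs <- split(tied, cumsum(c(1L, diff(tied) != 1L)))
    centers <- vapply(runs, function(r) mean(xs[r]), numeric(1))
    if (length(runs) == 1L) {
      loc <- centers[[1]]
      note <- "consecutive-tie minimum: plateau center used"
    } else {
      loc <- centers[[which.min(abs(centers))]]
      note <- "non-consecutive tied minima: broken toward 0 mm"
    }
  }
  if (which.min(ys) %in% c(1L, length(ys)) && length(tied) == 1L)
    note <- c(note, "monotone segment between peaks: endpoint minimum")
  list(location = unname(loc), flow = mn, note = note)
}

#' Half-maximum rostro-caudal injury extent
#'
#' On each side, the half-maximum level is the average of that side's
#' penumbra flow and the umbra flow; walking from the umbra toward the
#' penumbra, the crossing is located by linear interpolation between the
#' bracketing bins. The extent is the caudal crossing minus the rostral
#' crossing.
#'
#' @param profile a \linkS4class{SpatialProfile}.
#' @param umbraLocation,umbraFlow the labeled epicenter.
#' @param penumbraLocation,penumbraFlow named vectors
#'   \code{c(rostral=, caudal=)}.
#' @return list with \code{extent} (mm) and \code{crossings} (named mm
#'   pair); \code{NA}s when a side has no crossing (labeling failure).
#' @export
halfMaxExtent <- function(profile, umbraLocation, umbraFlow,
                          penumbraLocation, penumbraFlow) {
  stopifnot(is(profile, "SpatialProfile"))
  keep <- is.finite(profile@indexValues)
  x <- profile@binCenters[keep]
  y <- profile@indexValues[keep]
  crossing <- function(side) {
    thr <- unname((penumbraFlow[side] + umbraFlow) / 2)
    pl <- penumbraLocation[side]
    if (side == "rostral") {
      sel <- which(x >= pl & x <= umbraLocation)
      ord <- rev(sel)                   # walk rostralward from the umbra
    } else {
      sel <- which(x >= umbraLocation & x <= pl)
      ord <- sel
    }
    if (length(ord) < 2L) return(NA_real_)
    prev <- ord[1]
    for (i in ord[-1]) {
      if (y[i] >= thr && y[prev] < thr) {
        return(x[prev] + (thr - y[prev]) * (x[i] - x[prev]) /
                 (y[i] - y[prev]))
      }
      prev <- i
    }
    # the bin nearest the umbra may already sit at/above threshold
    if (y[ord[1]] >= thr) return(x[ord[1]])
    NA_real_
  }
  cr <- c(rostral = crossing("rostral"), caudal = crossing("caudal"))
  list(extent = unname(cr["caudal"] - cr["rostral"]), crossings = cr)
}

#' Mean flow of the distal regions
#'
#' Distal (presumably unaffected) tissue: all bins strictly rostral to the
#' rostral penumbra and strictly caudal to the caudal penumbra. A side with
#' no distal bins is reported missing (\code{NA}), never zero.
#'
#' @param profile a \linkS4class{SpatialProfile}.
#' @param penumbraLocation named mm pair \code{c(rostral=, caudal=)}.
#' @return named numeric \code{c(rostral=, caudal=)}.
#' @export
distalFlows <- function(profile, penumbraLocation) {
  stopifnot(is(profile, "SpatialProfile"))
  keep <- is.finite(profile@indexValues)
  x <- profile@binCenters[keep]
  y <- profile@indexValues[keep]
  ros <- y[x < penumbraLocation["rostral"]]
  cau <- y[x > penumbraLocation["caudal"]]
  c(rostral = if (length(ros)) mean(ros) else NA_real_,
    caudal = if (length(cau)) mean(cau) else NA_real_)
}

.emptyZoneLabels <- function(notes) {
  nap <- c(rostral = NA_real_, caudal = NA_real_)
  new("ZoneLabels", umbraLocation = NA_real_, umbraFlow = NA_real_,
      penumbraLocation = nap, penumbraFlow = nap,
      penumbraProminence = nap, distalFlow = nap,
      injuryExtent = NA_real_, halfMaxPoints = nap,
      labelingOk = FALSE, notes = notes)
}

#' Label all injury zones of a post-injury spatial profile
#'
#' Orchestrates the full zone analysis: penumbra peaks by prominence, umbra
#' between them, penumbra prominences (penumbra minus umbra flow),
#' half-maximum injury extent, and distal means.
#'
#' @param profile a (smoothed) post-injury \linkS4class{SpatialProfile}.
#' @param minProminence minimum peak prominence (0.03 AU).
#' @return a \linkS4class{ZoneLabels}.
#' @export
labelZones <- function(profile, minProminence = 0.03) {
  pks <- findPenumbraPeaks(profile, minProminence)
  if (!pks$labelingOk) {
    side <- c(if (is.null(pks$rostral)) "rostral",
              if (is.null(pks$caudal)) "caudal")
    return(.emptyZoneLabels(
      sprintf("no qualifying peak on the %s side",
              paste(side, collapse = " and "))))
  }
  penLoc <- c(rostral = unname(pks$rostral["location"]),
              caudal = unname(pks$caudal["location"]))
  penFlow <- c(rostral = unname(pks$rostral["flow"]),
               caudal = unname(pks$caudal["flow"]))
  um <- locateUmbra(profile, penLoc["rostral"], penLoc["caudal"])
  ext <- halfMaxExtent(profile, um$location, um$flow, penLoc, penFlow)
  notes <- um$note
  ok <- TRUE
  if (!is.finite(ext$extent) || ext$extent <= 0) {
    notes <- c(notes, "no usable half-maximum crossing")
    ok <- FALSE
  }
  dist <- distalFlows(profile, penLoc)
  if (any(!is.finite(dist)))
    notes <- c(notes, "a distal side has no bins (reported missing)")
  new("ZoneLabels",
      umbraLocation = um$location, umbraFlow = um$flow,
      penumbraLocation = penLoc, penumbraFlow = penFlow,
      penumbraProminence = penFlow - um$flow,
      distalFlow = dist,
      injuryExtent = ext$extent, halfMaxPoints = ext$crossings,
      labelingOk = ok, notes = notes)
}

#' Evaluate zone parameters on a pre-injury profile at post-injury locations
#'
#' Pre-injury umbra/penumbra flows, prominences and distal means are read
#' from the pre-injury profile at the locations labeled on the post-injury
#' profile, so pre and post values describe the same tissue. The two
#' profiles must share their bin grid. The half-maximum extent is not
#' defined pre-injury and is reported \code{NA}.
#'
#' @param preProfile pre-injury \linkS4class{SpatialProfile}.
#' @param postLabels \linkS4class{ZoneLabels} from the post-injury profile.
#' @param binTolerance grid agreement tolerance, mm.
#' @return a \linkS4class{ZoneLabels} evaluated on the pre-injury profile.
#' @export
preInjuryParameters <- function(preProfile, postLabels,
                                binTolerance = 1e-6) {
  stopifnot(is(preProfile, "SpatialProfile"), is(postLabels, "ZoneLabels"))
  if (!isTRUE(postLabels@labelingOk))
    return(.emptyZoneLabels("post-injury labeling failed"))
  lookup <- function(loc) {
    i <- which.min(abs(preProfile@binCenters - loc))
    if (abs(preProfile@binCenters[i] - loc) >
        preProfile@binWidth / 2 + binTolerance)
      stop("post-injury location outside the pre-injury profile grid")
    preProfile@indexValues[i]
  }
  umFlow <- lookup(postLabels@umbraLocation)
  penFlow <- c(rostral = lookup(postLabels@penumbraLocation["rostral"]),
               caudal = lookup(postLabels@penumbraLocation["caudal"]))
  dist <- distalFlows(preProfile, postLabels@penumbraLocation)
  new("ZoneLabels",
      umbraLocation = postLabels@umbraLocation, umbraFlow = umFlow,
      penumbraLocation = postLabels@penumbraLocation,
      penumbraFlow = penFlow,
      penumbraProminence = penFlow - umFlow,
      distalFlow = dist,
      injuryExtent = NA_real_,
      halfMaxPoints = c(rostral = NA_real_, caudal = NA_real_),
      labelingOk = TRUE,
      notes = "pre-injury values at post-injury locations")
}
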