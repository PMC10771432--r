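#' @import methods
NULL

#' FrameStack: a single-modality ultrasound recording
#'
#' Container for a stack of co-registered frames from one imaging modality,
#' together with its temporal and spatial calibration. Frames are stored as an
#' \code{H x W x T} numeric array (rows x columns x frames).
#'
#' @slot data numeric array, \code{H x W x T}, non-negative finite intensities.
#'   Velocity index (AU) for non-contrast recordings, microbubble intensity
#'   (AU) for contrast-harmonic recordings.
#' @slot fps frames per second (> 0).
#' @slot pixelSize pixel edge length in mm (> 0).
#' @slot modality \code{"noncontrast"} or \code{"contrast"}.
#' @slot meta free-form list (generator configuration, ground-truth linkage).
#'
#' @exportClass FrameStack
setClass("FrameStack",
  representation(data = "array", fps = "numeric", pixelSize = "numeric",
                 modality = "character", meta = "list"),
  prototype(meta = list()))

setValidity("FrameStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be an H x W x T array")
  if (dim(d)[3] < 1L) return("stack must contain at least one frame")
  if (!all(is.finite(d))) return("data must be finite")
  if (min(d) < 0) return("data must be non-negative")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (!object@modality %in% c("noncontrast", "contrast"))
    return("modality must be 'noncontrast' or 'contrast'")
  TRUE
})

#' FlowMap: a per-pixel flow-surrogate image
#'
#' A single \code{H x W} map of a flow surrogate: time-averaged velocity index
#' (AU) for the non-contrast arm, or washout decay constant (1/s) for the
#' contrast arm. Pixels where the surrogate could not be estimated are marked
#' invalid and carry the value 0.
#'
#' @slot values numeric matrix, non-negative.
#' @slot units \code{"AU"} (velocity index) or \code{"1/s"} (decay constant).
#' @slot validMask logical matrix, same shape as \code{values}.
#' @slot pixelSize mm per pixel.
#'
#' @exportClass FlowMap
setClass("FlowMap",
  representation(values = "matrix", units = "character",
                 validMask = "matrix", pixelSize = "numeric"))

setValidity("FlowMap", function(object) {
  v <- object@values
  if (!is.numeric(v) || !all(is.finite(v))) return("values must be finite")
  if (min(v) < 0) return("values must be non-negative")
  if (!identical(dim(v), dim(object@validMask)))
    return("validMask shape must match values")
  if (!is.logical(object@validMask)) return("validMask must be logical")
  if (any(v[!object@validMask] != 0)) return("invalid pixels must carry 0")
  if (!object@units %in% c("AU", "1/s"))
    return("units must be 'AU' or '1/s'")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' InjuryGeometry: injury line and cord borders
#'
#' User-drawn annotation of a recording: the injury marked as a line segment
#' transverse to the long (rostro-caudal) axis of the cord, and the dorsal and
#' ventral cord borders as polylines that bound the region of interest and
#' exclude the anterior/posterior spinal arteries. Coordinates are pixel
#' coordinates \code{(x = column, y = row)}, 1-based.
#'
#' @slot injuryLine 2 x 2 numeric matrix; rows are the two endpoints,
#'   columns are (x, y).
#' @slot upperBorder n x 2 matrix of (x, y) vertices, smaller y = nearer the
#'   top of the image.
#' @slot lowerBorder m x 2 matrix of (x, y) vertices.
#' @slot pixelSize mm per pixel.
#'
#' @exportClass InjuryGeometry
setClass("InjuryGeometry",
  representation(injuryLine = "matrix", upperBorder = "matrix",
                 lowerBorder = "matrix", pixelSize = "numeric"))

setValidity("InjuryGeometry", function(object) {
  L <- object@injuryLine
  if (!identical(dim(L), c(2L, 2L))) return("injuryLine must be 2 x 2")
  if (sqrt(sum((L[2, ] - L[1, ])^2)) < .Machine$double.eps^0.5)
    return("injury line is degenerate (zero length)")
  for (b in list(object@upperBorder, object@lowerBorder)) {
    if (ncol(b) != 2L || nrow(b) < 1L) return("borders must be n x 2 matrices")
    if (!all(is.finite(b))) return("border coordinates must be finite")
  }
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  xs <- range(c(object@upperBorder[, 1], object@lowerBorder[, 1]))
  probe <- seq(xs[1], xs[2], length.out = 101L)
  up <- .interpBorder(object@upperBorder, probe)
  lo <- .interpBorder(object@lowerBorder, probe)
  if (any(up > lo + 1e-9)) return("borders cross (upper below lower)")
  TRUE
})

#' SpatialProfile: flow versus signed distance from injury
#'
#' The central object of the pipeline: area-adjusted flow in fixed-width bins
#' of signed distance from the injury line (rostral negative, caudal
#' positive). Bins with no pixels are flagged by \code{NA} values and a zero
#' pixel count, never silently zeroed.
#'
#' @slot binCenters strictly increasing, uniformly spaced bin centers (mm).
#' @slot indexValues area-adjusted flow index per bin (AU or 1/s); \code{NA}
#'   marks an empty bin.
#' @slot binCounts integer pixel count per bin.
#' @slot binWidth bin width in mm (default pipeline uses 0.1).
#' @slot units \code{"AU"} or \code{"1/s"}.
#'
#' @exportClass SpatialProfile
setClass("SpatialProfile",
  representation(binCenters = "numeric", indexValues = "numeric",
                 binCounts = "integer", binWidth = "numeric",
                 units = "character"))

setValidity("SpatialProfile", function(object) {
  bc <- object@binCenters
  n <- length(bc)
  if (n < 1L) return("profile must have at least one bin")
  if (length(object@indexValues) != n || length(object@binCounts) != n)
    return("binCenters, indexValues and binCounts must share length")
  if (n > 1L) {
    sp <- diff(bc)
    if (any(sp <= 0)) return("binCenters must be strictly increasing")
    if (max(abs(sp - object@binWidth)) > 1e-6 * object@binWidth)
      return("binCenters must be uniformly spaced by binWidth")
  }
  ok <- is.finite(object@indexValues)
  if (any(object@indexValues[ok] < 0)) return("indexValues must be >= 0")
  if (any(object@binCounts < 0L)) return("binCounts must be >= 0")
  TRUE
})

#' ZoneLabels: injury-zone parameters from one spatial profile
#'
#' Locations and flows of the umbra (epicenter), the rostral and caudal
#' penumbras (nearest sufficiently prominent peak on each side of the injury),
#' penumbra prominences, mean distal flows, and the half-maximum
#' rostro-caudal injury extent. When labeling fails (e.g. a side has no
#' qualifying peak), \code{labelingOk} is \code{FALSE} and dependent fields
#' are \code{NA}.
#'
#' @slot umbraLocation mm; \code{umbraFlow} its flow value.
#' @slot umbraFlow numeric.
#' @slot penumbraLocation named numeric, \code{c(rostral=, caudal=)}, mm.
#' @slot penumbraFlow named numeric as above.
#' @slot penumbraProminence named numeric: penumbra flow minus umbra flow.
#' @slot distalFlow named numeric: mean flow beyond each penumbra.
#' @slot injuryExtent mm between the two half-maximum crossings.
#' @slot halfMaxPoints named numeric: the two crossing locations (mm).
#' @slot labelingOk logical.
#' @slot notes character vector of QC annotations (e.g. monotone segment,
#'   tie-broken minima, missing distal bins).
#'
#' @exportClass ZoneLabels
setClass("ZoneLabels",
  representation(umbraLocation = "numeric", umbraFlow = "numeric",
                 penumbraLocation = "numeric", penumbraFlow = "numeric",
                 penumbraProminence = "numeric", distalFlow = "numeric",
                 injuryExtent = "numeric", halfMaxPoints = "numeric",
                 labelingOk = "logical", notes = "character"),
  prototype(notes = character()))

setValidity("ZoneLabels", function(object) {
  for (s in c("penumbraLocation", "penumbraFlow", "penumbraProminence",
              "distalFlow", "halfMaxPoints")) {
    v <- slot(object, s)
    if (length(v) != 2L || !identical(names(v), c("rostral", "caudal")))
      return(sprintf("%s must be named c(rostral=, caudal=)", s))
  }
  if (isTRUE(object@labelingOk)) {
    pl <- object@penumbraLocation
    if (!(pl["rostral"] < object@umbraLocation &&
          object@umbraLocation < pl["caudal"]))
      return("rostral penumbra < umbra < caudal penumbra must hold")
    if (is.finite(object@injuryExtent) && object@injuryExtent <= 0)
      return("injuryExtent must be positive when labeling succeeded")
  }
  TRUE
})

#' GroundTruthProfile: analytic post-injury flow profile
#'
#' Parametric ground truth for phantom scenes: a flat distal baseline, a
#' Gaussian flow deficit at the injury epicenter (umbra), and a Gaussian flow
#' excess on each side (rostral and caudal penumbras). Widths are Gaussian
#' standard deviations in mm.
#'
#' @slot baselineFlow AU; distal flow level.
#' @slot umbraCenter mm; epicenter offset from the injury line.
#' @slot umbraDepth AU; depth of the central dip (<= baselineFlow).
#' @slot umbraWidth mm; sd of the dip.
#' @slot penumbraOffsets mm pair (rostral negative, caudal positive),
#'   relative to \code{umbraCenter}.
#' @slot penumbraHeights AU pair.
#' @slot penumbraWidth mm; sd of the flanking bumps.
#'
#' @exportClass GroundTruthProfile
setClass("GroundTruthProfile",
  representation(baselineFlow = "numeric", umbraCenter = "numeric",
                 umbraDepth = "numeric", umbraWidth = "numeric",
                 penumbraOffsets = "numeric", penumbraHeights = "numeric",
                 penumbraWidth = "numeric"))

setValidity("GroundTruthProfile", function(object) {
  if (object@umbraDepth < 0 || object@umbraDepth > object@baselineFlow)
    return("umbraDepth must lie in [0, baselineFlow]")
  po <- object@penumbraOffsets
  if (length(po) != 2L || !(po[1] < 0 && po[2] > 0))
    return("penumbraOffsets must be c(rostral < 0, caudal > 0)")
  if (length(object@penumbraHeights) != 2L ||
      any(object@penumbraHeights < 0))
    return("penumbraHeights must be two non-negative values")
  if (object@umbraWidth <= 0 || object@penumbraWidth <= 0)
    return("widths must be positive")
  TRUE
})

#' PhantomScene: a synthetic injured-cord imaging scene
#'
#' A mid-sagittal vessel field (axial vessel, perpendicular sulcal-like
#' branches and a diffuse perforator field) between two cord borders, with an
#' injury line and an analytic \linkS4class{GroundTruthProfile} that defines
#' the true flow at every vessel pixel.
#'
#' @slot vesselMask logical H x W matrix, contained between the cord borders.
#' @slot trueFlow numeric H x W: ground-truth flow (AU), 0 off-vessel.
#' @slot geometry \linkS4class{InjuryGeometry}.
#' @slot truth \linkS4class{GroundTruthProfile}.
#' @slot pixelSize mm per pixel.
#' @slot config list of generator parameters including the seed.
#'
#' @exportClass PhantomScene
setClass("PhantomScene",
  representation(vesselMask = "matrix", trueFlow = "matrix",
                 geometry = "InjuryGeometry", truth = "GroundTruthProfile",
                 pixelSize = "numeric", config = "list"))

setValidity("PhantomScene", function(object) {
  if (!is.logical(object@vesselMask)) return("vesselMask must be logical")
  if (!identical(dim(object@vesselMask), dim(object@trueFlow)))
    return("vesselMask and trueFlow shapes must agree")
  L <- object@geometry@injuryLine
  d <- dim(object@vesselMask)
  if (any(L[, 1] < 1 | L[, 1] > d[2] | L[, 2] < 1 | L[, 2] > d[1]))
    return("injury line endpoints must lie inside the image")
  band <- roiMask(object@geometry, d)
  if (any(object@vesselMask & !band))
    return("vesselMask must be contained between the cord borders")
  TRUE
})

#' BolusKinetics: per-pixel microbubble bolus model
#'
#' Intensity is 0 before \code{arrivalTime}, ramps linearly to
#' \code{peakAmplitude} over \code{riseTime}, then decays as
#' \code{exp(-decayConstant * (t - tPeak))}.
#'
#' @slot arrivalTime s. @slot riseTime s. @slot peakAmplitude AU.
#' @slot decayConstant 1/s, >= 0.
#'
#' @exportClass BolusKinetics
setClass("BolusKinetics",
  representation(arrivalTime = "numeric", riseTime = "numeric",
                 peakAmplitude = "numeric", decayConstant = "numeric"))

setValidity("BolusKinetics", function(object) {
  if (object@decayConstant < 0) return("decayConstant must be >= 0")
  if (object@arrivalTime < 0 || object@riseTime <= 0)
    return("arrivalTime must be >= 0 and riseTime > 0")
  if (object@peakAmplitude < 0) return("peakAmplitude must be >= 0")
  TRUE
})

#' DecayFitResult: per-pixel exponential washout fit
#'
#' @slot decayConstant 1/s, >= 0; 0 whenever \code{fitOk} is \code{FALSE}.
#' @slot peakTime s. @slot peakValue AU.
#' @slot fitOk logical; \code{FALSE} for unperfused pixels (sub-threshold
#'   peak, late peak, or too few usable post-peak samples).
#' @slot rss residual sum of squares of the fitted model (intensity scale).
#'
#' @exportClass DecayFitResult
setClass("DecayFitResult",
  representation(decayConstant = "numeric", peakTime = "numeric",
                 peakValue = "numeric", fitOk = "logical", rss = "numeric"))

setValidity("DecayFitResult", function(object) {
  if (object@decayConstant < 0) return("decayConstant must be >= 0")
  if (!object@fitOk && object@decayConstant != 0)
    return("failed fits must carry decayConstant 0")
  TRUE
})

#' ZoneTimeSeries: frame-by-frame zone tracking
#'
#' Per-frame zone locations (raw and median-filtered) and flows for
#' continuous recordings.
#'
#' @slot times frame times, s.
#' @slot locationRaw T x 3 matrix (umbra, rostralPenumbra, caudalPenumbra),
#'   mm; \code{NA} where labeling failed.
#' @slot locationFiltered same shape, after the running-median filter.
#' @slot flow T x 5 matrix (umbra, rostralPenumbra, caudalPenumbra,
#'   rostralDistal, caudalDistal) sampled at the filtered locations.
#' @slot labelingOk logical per frame.
#' @slot filterWindow median filter size (frames).
#'
#' @exportClass ZoneTimeSeries
setClass("ZoneTimeSeries",
  representation(times = "numeric", locationRaw = "matrix",
                 locationFiltered = "matrix", flow = "matrix",
                 labelingOk = "logical", filterWindow = "numeric"))

setValidity("ZoneTimeSeries", function(object) {
  n <- length(object@times)
  if (nrow(object@locationRaw) != n || nrow(object@locationFiltered) != n ||
      nrow(object@flow) != n || length(object@labelingOk) != n)
    return("all traces must share the number of frames")
  TRUE
})

#' CorrelationResult: rank correlation between two profiles
#'
#' @slot rho Spearman rank correlation in [-1, 1].
#' @slot pValue two-sided p-value.
#' @slot nBins number of shared (non-missing) bins used.
#'
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(rho = "numeric", pValue = "numeric", nBins = "integer"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@rho) > 1 + 1e-12) return("|rho| must be <= 1")
  if (object@nBins < 3L) return("nBins must be >= 3")
  TRUE
})
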