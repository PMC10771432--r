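#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("frameData", "FrameStack", function(object) object@data)
#' @rdname accessors
setMethod("fps", "FrameStack", function(object) object@fps)
#' @rdname accessors
setMethod("pixelSize", "FrameStack", function(object) object@pixelSize)
#' @rdname accessors
setMethod("modality", "FrameStack", function(object) object@modality)
#' @rdname accessors
setMethod("nFrames", "FrameStack", function(object) dim(object@data)[3L])

#' @rdname accessors
setMethod("flowValues", "FlowMap", function(object) object@values)
#' @rdname accessors
setMethod("flowUnits", "FlowMap", function(object) object@units)
#' @rdname accessors
setMethod("validMask", "FlowMap", function(object) object@validMask)
#' @rdname accessors
setMethod("pixelSize", "FlowMap", function(object) object@pixelSize)

#' @rdname accessors
setMethod("binCenters", "SpatialProfile", function(object) object@binCenters)
#' @rdname accessors
setMethod("indexValues", "SpatialProfile", function(object) object@indexValues)
#' @rdname accessors
setMethod("binCounts", "SpatialProfile", function(object) object@binCounts)
#' @rdname accessors
setMethod("binWidth", "SpatialProfile", function(object) object@binWidth)
#' @rdname accessors
setMethod("flowUnits", "SpatialProfile", function(object) object@units)

#' @rdname accessors
setMethod("vesselMask", "PhantomScene", function(object) object@vesselMask)
#' @rdname accessors
setMethod("trueFlow", "PhantomScene", function(object) object@trueFlow)
#' @rdname accessors
setMethod("sceneTruth", "PhantomScene", function(object) object@truth)
#' @rdname accessors
setMethod("injuryGeometry", "PhantomScene", function(object) object@geometry)
#' @rdname accessors
setMethod("pixelSize", "PhantomScene", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "InjuryGeometry", function(object) object@pixelSize)

#' @rdname accessors
setMethod("labelingOk", "ZoneLabels", function(object) object@labelingOk)
#' @rdname accessors
setMethod("injuryExtent", "ZoneLabels", function(object) object@injuryExtent)

#' @rdname accessors
setMethod("decayConstant", "DecayFitResult",
          function(object) object@decayConstant)
#' @rdname accessors
setMethod("fitOk", "DecayFitResult", function(object) object@fitOk)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack: %d x %d px, %d frames @ %g fps (%s), %g mm/px\n",
              d[1], d[2], d[3], object@fps, object@modality,
              object@pixelSize))
})

setMethod("show", "FlowMap", function(object) {
  cat(sprintf("FlowMap [%s]: %d x %d px, %g mm/px, %d valid px, max %.4g\n",
              object@units, nrow(object@values), ncol(object@values),
              object@pixelSize, sum(object@validMask), max(object@values)))
})

setMethod("show", "SpatialProfile", function(object) {
  n <- length(object@binCenters)
  cat(sprintf(
    "SpatialProfile [%s]: %d bins of %g mm, %.2f to %.2f mm, %d missing\n",
    object@units, n, object@binWidth, object@binCenters[1],
    object@binCenters[n], sum(!is.finite(object@indexValues))))
})

setMethod("show", "ZoneLabels", function(object) {
  if (!isTRUE(object@labelingOk)) {
    cat("ZoneLabels: labeling failed",
        if (length(object@notes)) paste0("(", object@notes[1], ")"), "\n")
    return(invisible(NULL))
  }
  cat(sprintf("ZoneLabels: umbra %.2f mm (flow %.3g)\n",
              object@umbraLocation, object@umbraFlow))
  cat(sprintf("  penumbra rostral %.2f mm / caudal %.2f mm, prominence %.3g / %.3g\n",
              object@penumbraLocation["rostral"],
              object@penumbraLocation["caudal"],
              object@penumbraProminence["rostral"],
              object@penumbraProminence["caudal"]))
  cat(sprintf("  distal flow %.3g / %.3g, injury extent %.2f mm\n",
              object@distalFlow["rostral"], object@distalFlow["caudal"],
              object@injuryExtent))
})

setMethod("show", "PhantomScene", function(object) {
  d <- dim(object@vesselMask)
  cat(sprintf("PhantomScene: %d x %d px (%g mm/px), %d vessel px, seed %s\n",
              d[1], d[2], object@pixelSize, sum(object@vesselMask),
              deparse(object@config$seed)))
})

setMethod("show", "DecayFitResult", function(object) {
  cat(sprintf("DecayFitResult: k = %.4g 1/s, peak %.3g AU at %.2f s, %s\n",
              object@decayConstant, object@peakValue, object@peakTime,
              if (object@fitOk) "fit ok" else "zero-assigned"))
})

setMethod("show", "ZoneTimeSeries", function(object) {
  cat(sprintf("ZoneTimeSeries: %d frames, %.1f s, %d labeled, filter %d frames\n",
              length(object@times), max(object@times), sum(object@labelingOk),
              as.integer(object@filterWindow)))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman rho = %.3f (p = %.3g, %d bins)\n",
              object@rho, object@pValue, object@nBins))
})

#' Flatten a ZoneLabels object to a one-row data frame
#'
#' Tidy export of all zone parameters for one recording, suitable for
#' rbinding across subjects and feeding external statistics.
#'
#' @param labels a \linkS4class{ZoneLabels}.
#' @return one-row \code{data.frame}.
#' @export
zoneTable <- function(labels) {
  stopifnot(is(labels, "ZoneLabels"))
  data.frame(
    umbra_location_mm = labels@umbraLocation,
    umbra_flow = labels@umbraFlow,
    rostral_penumbra_location_mm = unname(labels@penumbraLocation["rostral"]),
    caudal_penumbra_location_mm = unname(labels@penumbraLocation["caudal"]),
    rostral_penumbra_flow = unname(labels@penumbraFlow["rostral"]),
    caudal_penumbra_flow = unname(labels@penumbraFlow["caudal"]),
    rostral_prominence = unname(labels@penumbraProminence["rostral"]),
    caudal_prominence = unname(labels@penumbraProminence["caudal"]),
    rostral_distal_flow = unname(labels@distalFlow["rostral"]),
    caudal_distal_flow = unname(labels@distalFlow["caudal"]),
    injury_extent_mm = labels@injuryExtent,
    labeling_ok = labels@labelingOk)
}

#' Long-format data frame of a ZoneTimeSeries
#'
#' @param x a \linkS4class{ZoneTimeSeries}.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return \code{data.frame} with columns frame, time_s, zone, location_mm
#'   (NA for distal zones), flow.
#' @export
as.data.frame.ZoneTimeSeries <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  n <- length(x@times)
  zones <- colnames(x@flow)
  loc <- cbind(x@locationFiltered,
               matrix(NA_real_, n, 2,
                      dimnames = list(NULL, c("rostralDistal", "caudalDistal"))))
  out <- do.call(rbind, lapply(zones, function(z) {
    data.frame(frame = seq_len(n), time_s = x@times, zone = z,
               location_mm = loc[, z], flow = x@flow[, z])
  }))
  rownames(out) <- NULL
  out
}
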