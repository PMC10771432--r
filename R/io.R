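#' @include AllClasses.R
NULL

#' Write a FrameStack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are scaled into [0, 1] for 32-bit TIFF storage; the scale factor,
#' frame rate, pixel size and modality go into \code{<path>.json} so the
#' stack round-trips exactly.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path output TIFF path; the sidecar is \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@data)
  scale <- max(stack@data, 1e-12)
  frames <- lapply(seq_len(d[3]), function(k) stack@data[, , k] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(fps = stack@fps, pixelSize = stack@pixelSize,
         modality = stack@modality, scale = scale, nFrames = d[3]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FrameStack written by \code{\link{writeFrameStack}}
#'
#' Also reads plain grayscale multi-page TIFFs from other sources: supply
#' \code{fps}, \code{pixelSize} and \code{modality} when no sidecar exists.
#'
#' @param path TIFF path.
#' @param fps,pixelSize,modality overrides / values for sidecar-less files.
#' @return a \linkS4class{FrameStack}.
#' @export
readFrameStack <- function(path, fps = NULL, pixelSize = NULL,
                           modality = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f[, , 1] else f   # tolerate gray-as-RGB
  })
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  fps <- if (!is.null(fps)) fps else meta$fps
  pixelSize <- if (!is.null(pixelSize)) pixelSize else meta$pixelSize
  modality <- if (!is.null(modality)) modality else meta$modality
  if (is.null(fps) || is.null(pixelSize) || is.null(modality))
    stop("fps, pixelSize and modality must come from the sidecar or caller")
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  data <- array(unlist(frames), dim = c(H, W, length(frames))) * scale
  new("FrameStack", data = data, fps = fps, pixelSize = pixelSize,
      modality = modality)
}

#' Read / write injury geometry as JSON
#'
#' The annotation format: injury line endpoints, border vertex lists and
#' the pixel calibration.
#'
#' @param geometry an \linkS4class{InjuryGeometry}.
#' @param path JSON file path.
#' @return \code{readInjuryGeometry}: an \linkS4class{InjuryGeometry};
#'   \code{writeInjuryGeometry}: \code{path}, invisibly.
#' @name geometryIO
#' @export
writeInjuryGeometry <- function(geometry, path) {
  stopifnot(is(geometry, "InjuryGeometry"))
  jsonlite::write_json(
    list(injury_line = unname(apply(geometry@injuryLine, 1, as.list)),
         upper_border = unname(apply(geometry@upperBorder, 1, as.list)),
         lower_border = unname(apply(geometry@lowerBorder, 1, as.list)),
         pixel_size_mm = geometry@pixelSize),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometryIO
#' @export
readInjuryGeometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(x) {
    m <- if (is.matrix(x)) x
         else if (is.data.frame(x)) as.matrix(x)
         else do.call(rbind, x)
    matrix(as.numeric(m), nrow = nrow(m))
  }
  new("InjuryGeometry",
      injuryLine = toMat(j$injury_line),
      upperBorder = toMat(j$upper_border),
      lowerBorder = toMat(j$lower_border),
      pixelSize = j$pixel_size_mm)
}

#' Read / write a spatial profile as CSV
#'
#' Columns: \code{bin_center_mm}, \code{index}, \code{n_pixels}. Missing
#' bins keep \code{NA} in \code{index}.
#'
#' @param profile a \linkS4class{SpatialProfile}.
#' @param path CSV path.
#' @param units units string for \code{readProfileCsv} (not stored in CSV).
#' @return \code{readProfileCsv}: a \linkS4class{SpatialProfile};
#'   \code{writeProfileCsv}: \code{path}, invisibly.
#' @name profileIO
#' @export
writeProfileCsv <- function(profile, path) {
  stopifnot(is(profile, "SpatialProfile"))
  utils::write.csv(
    data.frame(bin_center_mm = profile@binCenters,
               index = profile@indexValues,
               n_pixels = profile@binCounts),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname profileIO
#' @export
readProfileCsv <- function(path, units = "AU") {
  d <- utils::read.csv(path)
  bw <- if (nrow(d) > 1L) stats::median(diff(d$bin_center_mm)) else 0.1
  new("SpatialProfile", binCenters = d$bin_center_mm,
      indexValues = d$index, binCounts = as.integer(d$n_pixels),
      binWidth = bw, units = units)
}

#' Read a color-to-velocity-index lookup table from CSV
#'
#' Expected columns: \code{R, G, B, index}, colors in [0, 255] or [0, 1].
#'
#' @param path CSV path.
#' @return data frame with columns \code{r, g, b, index}.
#' @export
readLut <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  stopifnot(all(c("r", "g", "b", "index") %in% names(d)))
  if (max(d$r, d$g, d$b) > 1) d[c("r", "g", "b")] <- d[c("r", "g", "b")] / 255
  d[c("r", "g", "b", "index")]
}

#' Write a phantom scene's ground truth sidecar
#'
#' Serializes the scene truth, geometry, calibration and generator config
#' to JSON (the TIFF stacks are written separately from rendered
#' \linkS4class{FrameStack}s).
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSceneTruth <- function(scene, path) {
  stopifnot(is(scene, "PhantomScene"))
  tr <- scene@truth
  jsonlite::write_json(
    list(truth = list(baseline_flow = tr@baselineFlow,
                      umbra_center = tr@umbraCenter,
                      umbra_depth = tr@umbraDepth,
                      umbra_width = tr@umbraWidth,
                      penumbra_offsets = tr@penumbraOffsets,
                      penumbra_heights = tr@penumbraHeights,
                      penumbra_width = tr@penumbraWidth),
         injury_line = unname(apply(scene@geometry@injuryLine, 1, as.list)),
         pixel_size_mm = scene@pixelSize,
         config = scene@config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
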