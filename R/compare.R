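#' @include AllClasses.R
NULL

.sharedBins <- function(a, b) {
  stopifnot(is(a, "SpatialProfile"), is(b, "SpatialProfile"))
  if (abs(a@binWidth - b@binWidth) > 1e-9)
    stop("profiles have different bin widths")
  common <- intersect(round(a@binCenters / a@binWidth * 2),
                      round(b@binCenters / b@binWidth * 2))
  ia <- match(common, round(a@binCenters / a@binWidth * 2))
  ib <- match(common, round(b@binCenters / b@binWidth * 2))
  keep <- is.finite(a@indexValues[ia]) & is.finite(b@indexValues[ib])
  list(a = a@indexValues[ia][keep], b = b@indexValues[ib][keep],
       centers = a@binCenters[ia][keep])
}

#' Spearman rank correlation between two spatial profiles
#'
#' Per-subject cross-modality agreement: rank correlation (average ranks on
#' ties) of the two modalities' values over shared distance bins, chosen to
#' test monotonicity without any linearity assumption. Bins missing in
#' either profile are dropped pairwise.
#'
#' @param a,b \linkS4class{SpatialProfile}s on the same bin grid (units may
#'   differ, e.g. AU versus 1/s).
#' @return a \linkS4class{CorrelationResult}.
#' @export
spearmanProfiles <- function(a, b) {
  s <- .sharedBins(a, b)
  if (length(s$a) < 3L) stop("fewer than 3 shared non-missing bins")
  ct <- suppressWarnings(
    stats::cor.test(s$a, s$b, method = "spearman", exact = FALSE))
  new("CorrelationResult", rho = unname(ct$estimate),
      pValue = ct$p.value, nBins = length(s$a))
}

#' Average correlations across subjects by Fisher's z transform
#'
#' \code{tanh(mean(atanh(rho)))}: each subject's rank correlation is mapped
#' to the z scale, averaged, and mapped back — the appropriate average when
#' per-subject correlations vary (as the contrast arm's do between
#' animals). A correlation of exactly +/-1 diverges on the z scale and is
#' rejected unless \code{clip = TRUE}, which clips it just inside the
#' interval with a warning.
#'
#' @param rhos numeric vector of per-subject correlations, each in (-1, 1).
#' @param n optional common number of bins per subject; when given, a
#'   z-scale test of the mean against 0 is attached as attributes
#'   \code{z} and \code{pTransform} (labeled as transform-domain, distinct
#'   from any per-subject p-value).
#' @param clip clip |rho| = 1 instead of erroring.
#' @return the averaged correlation (numeric scalar).
#' @export
fisherZMean <- function(rhos, n = NULL, clip = FALSE) {
  if (!length(rhos)) stop("no correlations supplied")
  if (any(abs(rhos) > 1)) stop("|rho| must be <= 1")
  if (any(abs(rhos) == 1)) {
    if (!clip) stop("|rho| = 1 diverges under atanh; set clip = TRUE")
    warning("clipping |rho| = 1 inside the open interval")
    rhos <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rhos))
  }
  z <- mean(atanh(rhos))
  out <- tanh(z)
  if (!is.null(n) && length(rhos) > 1L) {
    se <- 1 / sqrt((n - 3) * length(rhos))
    zstat <- z / se
    attr(out, "z") <- zstat
    attr(out, "pTransform") <- 2 * stats::pnorm(-abs(zstat))
  }
  out
}

#' Per-bin discrepancy curve between two modalities
#'
#' Because the two arms carry different units (velocity index AU versus
#' decay constant 1/s), each profile is first rescaled to [0, 1] by its own
#' maximum; the discrepancy is the per-bin absolute difference of the
#' rescaled profiles. The rescaling convention is this module's own.
#'
#' @param a,b \linkS4class{SpatialProfile}s on the same bin grid.
#' @return data frame with \code{bin_center_mm} and \code{discrepancy}.
#' @export
profileDiscrepancy <- function(a, b) {
  s <- .sharedBins(a, b)
  ma <- max(s$a); mb <- max(s$b)
  if (ma <= 0 || mb <= 0) stop("a profile has zero maximum; cannot rescale")
  data.frame(bin_center_mm = s$centers,
             discrepancy = abs(s$a / ma - s$b / mb))
}
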