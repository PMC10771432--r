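#' @include AllClasses.R profile.R
NULL

#' Default post-injury ground-truth profile
#'
#' Baseline flow 0.5 AU with a deep Gaussian dip at the epicenter
#' (depth 0.45 AU, sd 0.4 mm) and elevated-flow penumbral bumps at
#' +/- 2.0 mm (height 0.2 AU, sd 0.4 mm) — the canonical post-contusion
#' shape: abolished flow at the epicenter, hyperemic flanks, unchanged
#' distal tissue. The dip and bumps are separated by more than half the
#' 1 mm profile filter width, so filtering does not displace the extrema.
#'
#' @param baselineFlow,umbraCenter,umbraDepth,umbraWidth,penumbraOffsets,penumbraHeights,penumbraWidth
#'   see \linkS4class{GroundTruthProfile}.
#' @return a \linkS4class{GroundTruthProfile}.
#' @export
defaultTruth <- function(baselineFlow = 0.5, umbraCenter = 0,
                         umbraDepth = 0.45, umbraWidth = 0.4,
                         penumbraOffsets = c(-2, 2),
                         penumbraHeights = c(0.2, 0.2),
                         penumbraWidth = 0.4) {
  new("GroundTruthProfile", baselineFlow = baselineFlow,
      umbraCenter = umbraCenter, umbraDepth = umbraDepth,
      umbraWidth = umbraWidth, penumbraOffsets = penumbraOffsets,
      penumbraHeights = penumbraHeights, penumbraWidth = penumbraWidth)
}

#' Evaluate an analytic ground-truth profile
#'
#' @param truth a \linkS4class{GroundTruthProfile}.
#' @param d signed distances from the injury line, mm (vector or matrix).
#' @return true flow (AU) with the shape of \code{d}; equals
#'   \code{baselineFlow} far from the injury.
#' @export
evalTruthProfile <- function(truth, d) {
  stopifnot(is(truth, "GroundTruthProfile"))
  x <- d - truth@umbraCenter
  y <- truth@baselineFlow -
    truth@umbraDepth * exp(-x^2 / (2 * truth@umbraWidth^2)) +
    truth@penumbraHeights[1] *
      exp(-(x - truth@penumbraOffsets[1])^2 / (2 * truth@penumbraWidth^2)) +
    truth@penumbraHeights[2] *
      exp(-(x - truth@penumbraOffsets[2])^2 / (2 * truth@penumbraWidth^2))
  if (is.matrix(d)) dim(y) <- dim(d)
  y
}

#' True zone locations of an analytic profile
#'
#' Dense numeric evaluation of the ground truth: the penumbra peak nearest
#' the injury line on each side of 0 mm and the flow minimum between them.
#' Because the Gaussian components overlap, the true extrema sit slightly
#' away from the nominal parameters; this function is the reference the
#' labeling pipeline is validated against.
#'
#' @param truth a \linkS4class{GroundTruthProfile}.
#' @param span half-width of the evaluated domain, mm.
#' @param step grid step, mm.
#' @return list with \code{rostral}, \code{caudal}, \code{umbra} (mm) and
#'   the corresponding flows.
#' @export
truthZoneLocations <- function(truth, span = 5, step = 1e-4) {
  d <- seq(-span, span, by = step)
  y <- evalTruthProfile(truth, d)
  dy <- diff(y)
  pk <- which(dy[-length(dy)] > 0 & dy[-1] <= 0) + 1L
  pkd <- d[pk]
  ros <- pkd[pkd < 0]
  cau <- pkd[pkd > 0]
  if (!length(ros) || !length(cau))
    stop("truth profile has no penumbra peak on one side")
  ros <- max(ros)
  cau <- min(cau)
  between <- d > ros & d < cau
  um <- d[between][which.min(y[between])]
  list(rostral = ros, caudal = cau, umbra = um,
       rostralFlow = evalTruthProfile(truth, ros),
       caudalFlow = evalTruthProfile(truth, cau),
       umbraFlow = evalTruthProfile(truth, um))
}

#' Generate a synthetic injured-cord scene
#'
#' Builds a mid-sagittal vessel field between two gently undulating cord
#' borders: a horizontal axial vessel (anterior-spinal-artery-like) with
#' evenly spaced perpendicular branches (sulcal-artery-like) plus a diffuse
#' perforator field, a transverse injury line, and the analytic ground-truth
#' flow evaluated at each pixel's signed distance from that line.
#'
#' @param height,width image size in pixels (>= 64 each).
#' @param pixelSize mm per pixel.
#' @param truth a \linkS4class{GroundTruthProfile}.
#' @param perforatorPeriod period of the diagonal perforator lattice in px
#'   (density 1/period); the lattice offset is seed-jittered. A regular,
#'   dense capillary-scale field keeps per-bin vessel area uniform, as the
#'   in vivo perforator field is at the 0.1 mm analysis scale.
#' @param axialThickness axial vessel thickness, px.
#' @param branchSpacing branch spacing, mm.
#' @param branchWidth branch width, px.
#' @param injuryX injury line column; default image center.
#' @param seed RNG seed (required; generation is fully deterministic).
#' @return a \linkS4class{PhantomScene}.
#' @export
makeScene <- function(height = 96, width = 224, pixelSize = 0.05,
                      truth = defaultTruth(), perforatorPeriod = 2L,
                      axialThickness = 4, branchSpacing = 0.55,
                      branchWidth = 1, injuryX = NULL, seed) {
  if (height < 64 || width < 64) stop("dimensions must be at least 64 x 64")
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (missing(seed)) stop("a seed is required")
  withSeed(seed, {
    xsV <- seq(1, width, length.out = 9L)
    phase <- stats::runif(2, 0, 2 * pi)
    upper <- cbind(xsV, round(0.26 * height) +
                     1.5 * sin(2 * pi * xsV / width + phase[1]))
    lower <- cbind(xsV, round(0.80 * height) +
                     1.5 * sin(2 * pi * xsV / width + phase[2]))
    # half-pixel line position: distances then straddle bin centers
    # symmetrically instead of piling on bin edges
    if (is.null(injuryX)) injuryX <- round(width / 2) + 0.5
    geom <- new("InjuryGeometry",
                injuryLine = rbind(c(injuryX, 2), c(injuryX, height - 1)),
                upperBorder = upper, lowerBorder = lower,
                pixelSize = pixelSize)
    band <- roiMask(geom, c(height, width))
    rows <- matrix(seq_len(height), height, width)
    # constant-row axial vessel: keeps per-bin vessel area uniform along x
    midRow <- round(0.53 * height)
    axial <- abs(rows - midRow) <= axialThickness / 2
    spacingPx <- max(1L, round(branchSpacing / pixelSize))
    branchCols <- seq.int(from = sample.int(spacingPx, 1L), to = width,
                          by = spacingPx)
    # sulcal-like branches: descend from the axial vessel toward the
    # ventral border rather than spanning the whole band
    branch <- matrix(FALSE, height, width)
    for (bc in branchCols) {
      cols <- bc:min(width, bc + branchWidth - 1L)
      branch[rows[, 1] >= midRow, cols] <- TRUE
    }
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    # checkerboard-phase lattice: adjacent columns carry complementary
    # phases, so vessel density is uniform at the distance-bin scale
    latticeOff <- sample.int(perforatorPeriod, 1L) - 1L
    diffuse <- (rows + cols + latticeOff) %% perforatorPeriod == 0L
    vessel <- (axial | branch | diffuse) & band
    dmap <- signedDistanceMap(geom, c(height, width))
    flow <- evalTruthProfile(truth, dmap)
    flow[!vessel] <- 0
    new("PhantomScene", vesselMask = vessel, trueFlow = flow,
        geometry = geom, truth = truth, pixelSize = pixelSize,
        config = list(seed = seed, perforatorPeriod = perforatorPeriod,
                      axialThickness = axialThickness,
                      branchSpacing = branchSpacing,
                      branchWidth = branchWidth, injuryX = injuryX,
                      height = height, width = width))
  })
}

#' Render a non-contrast (SMI-like) recording of a scene
#'
#' Per-frame pixel value = true flow x cardiac modulation, degraded by
#' Doppler dropout (pixel-frame values set to 0) and additive noise on
#' vessel pixels. Off-vessel pixels are exactly 0 in every frame. The
#' cardiac modulation is a raised sinusoid of mean 1 (rat-like 5 Hz), so the
#' time average over whole cycles equals the true flow map.
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param nFrames number of frames (>= 1).
#' @param fps frame rate; the default 39 fps matches the SMI acquisition,
#'   5 s per averaged map.
#' @param dropout per-pixel-per-frame dropout probability.
#' @param additiveSd sd of additive Gaussian noise (AU), clipped at 0.
#' @param modAmplitude amplitude of the cardiac modulation.
#' @param modFreq cardiac frequency, Hz.
#' @param seed RNG seed (required).
#' @return a \linkS4class{FrameStack} with modality \code{"noncontrast"}.
#' @export
renderNoncontrast <- function(scene, nFrames = 195, fps = 39,
                              dropout = 0.15, additiveSd = 0.05,
                              modAmplitude = 0.3, modFreq = 5, seed) {
  stopifnot(is(scene, "PhantomScene"))
  if (nFrames < 1) stop("nFrames must be >= 1")
  if (fps <= 0) stop("fps must be positive")
  if (missing(seed)) stop("a seed is required")
  withSeed(seed, {
    H <- nrow(scene@trueFlow); W <- ncol(scene@trueFlow)
    vsel <- which(scene@vesselMask)
    base <- scene@trueFlow[vsel]
    tt <- (seq_len(nFrames) - 1) / fps
    phase <- stats::runif(1, 0, 2 * pi)
    mod <- 1 + modAmplitude * sin(2 * pi * modFreq * tt + phase)
    data <- array(0, dim = c(H, W, nFrames))
    nv <- length(vsel)
    for (k in seq_len(nFrames)) {
      v <- base * mod[k]
      if (dropout > 0) v[stats::runif(nv) < dropout] <- 0
      if (additiveSd > 0) v <- pmax(0, v + stats::rnorm(nv, 0, additiveSd))
      frame <- matrix(0, H, W)
      frame[vsel] <- v
      data[, , k] <- frame
    }
    new("FrameStack", data = data, fps = fps, pixelSize = scene@pixelSize,
        modality = "noncontrast",
        meta = list(sceneConfig = scene@config,
                    noise = list(dropout = dropout, additiveSd = additiveSd,
                                 modAmplitude = modAmplitude,
                                 modFreq = modFreq, seed = seed)))
  })
}

# Noise-free bolus time course for one decay constant.
.bolusCurve <- function(t, k, arrivalTime, riseTime, peakAmplitude) {
  tp <- arrivalTime + riseTime
  y <- numeric(length(t))
  ramp <- t >= arrivalTime & t < tp
  y[ramp] <- peakAmplitude * (t[ramp] - arrivalTime) / riseTime
  post <- t >= tp
  y[post] <- peakAmplitude * exp(-k * (t[post] - tp))
  y
}

#' Render microbubble bolus time-intensity curves
#'
#' Pixel-level generator: intensity is 0 before arrival, ramps linearly to
#' the peak, then decays as a first-order exponential with the given rate.
#' Additive Gaussian noise is truncated at +/- 5 sd (keeping unperfused
#' background strictly below the 0.015 AU max-intensity threshold) and the
#' result clipped at 0.
#'
#' @param k decay constant(s), 1/s.
#' @param fps frames per second.
#' @param duration recording length, s.
#' @param arrivalTime,riseTime,peakAmplitude bolus kinetics (s, s, AU).
#' @param additiveSd noise sd (AU); 0 for a noiseless curve.
#' @param seed RNG seed; required when \code{additiveSd > 0}.
#' @return numeric matrix, \code{T x length(k)} (a vector if one k).
#' @export
renderBolusSeries <- function(k, fps = 39, duration = 150, arrivalTime = 8,
                              riseTime = 7, peakAmplitude = 0.5,
                              additiveSd = 0, seed = NULL) {
  if (fps <= 0) stop("fps must be positive")
  if (duration < 2 * riseTime)
    stop("duration must be at least twice the rise time")
  t <- (seq_len(floor(duration * fps)) - 1) / fps
  clean <- vapply(k, function(kk)
    .bolusCurve(t, kk, arrivalTime, riseTime, peakAmplitude),
    numeric(length(t)))
  if (additiveSd > 0) {
    if (is.null(seed)) stop("a seed is required when noise is on")
    clean <- withSeed(seed, {
      z <- stats::rnorm(length(clean))
      z <- pmin(5, pmax(-5, z))
      pmax(0, clean + additiveSd * z)
    })
    dim(clean) <- c(length(t), length(k))
  }
  if (length(k) == 1L) drop(clean) else clean
}

#' Render a contrast-harmonic bolus recording of a scene
#'
#' Microbubbles perfuse the capillary bed, so the contrast signal is
#' spatially dense: the perfusion field is the local (radius
#' \code{bedRadius}) mean of the scene's vessel flow over the cord band.
#' Every perfused pixel follows first-order bolus kinetics whose decay
#' constant is proportional to that local flow
#' (\code{k = kPerFlow * localFlow}); non-perfused pixels carry only
#' sub-threshold noise. The rendered per-pixel decay-constant field is
#' stored in \code{meta$kMap} as the ground truth for map validation.
#' Optional speckle injects isolated small blobs with fast artificial
#' washout to emulate microbubble aggregates (the artifact the offset-disk
#' opening removes).
#'
#' @param scene a \linkS4class{PhantomScene}.
#' @param duration recording length, s (contrast protocol: 150 s).
#' @param fps frame rate; contrast maps are rate-insensitive, default 4 fps.
#' @param arrivalTime,riseTime,peakAmplitude bolus kinetics.
#' @param kPerFlow proportionality between decay constant and local flow,
#'   (1/s) per AU; the default places decay constants on the 0.05-0.15 1/s
#'   scale implied by the 0.05 1/s structuring-element height of the map
#'   post-processing.
#' @param bedRadius capillary-bed averaging radius, px.
#' @param additiveSd additive noise sd (AU), truncated at 5 sd.
#' @param speckle \code{NULL}, or \code{list(n=, radius=, k=)}: number of
#'   blobs (radius in px, <= 2), each rendered as a bolus with the given
#'   artificially high decay constant.
#' @param seed RNG seed (required).
#' @return a \linkS4class{FrameStack} with modality \code{"contrast"}.
#' @export
renderContrast <- function(scene, duration = 150, fps = 4, arrivalTime = 8,
                           riseTime = 7, peakAmplitude = 0.5,
                           kPerFlow = 0.2, bedRadius = 2L,
                           additiveSd = 0.002, speckle = NULL, seed) {
  stopifnot(is(scene, "PhantomScene"))
  if (fps <= 0) stop("fps must be positive")
  if (duration < 2 * riseTime)
    stop("duration must be at least twice the rise time")
  if (missing(seed)) stop("a seed is required")
  withSeed(seed, {
    H <- nrow(scene@trueFlow); W <- ncol(scene@trueFlow)
    t <- (seq_len(floor(duration * fps)) - 1) / fps
    nT <- length(t)
    data <- array(0, dim = c(H, W, nT))
    band <- roiMask(scene@geometry, c(H, W))
    bed <- .diskMean(scene@trueFlow, as.integer(bedRadius))
    bed[!band] <- 0
    kField <- kPerFlow * bed
    vsel <- which(kField > 0)
    kmap <- kField[vsel]
    tp <- arrivalTime + riseTime
    # shared ramp, per-pixel washout
    rampIdx <- which(t >= arrivalTime & t < tp)
    postIdx <- which(t >= tp)
    ramp <- peakAmplitude * (t[rampIdx] - arrivalTime) / riseTime
    perfused <- matrix(0, length(vsel), nT)
    if (length(rampIdx))
      perfused[, rampIdx] <- matrix(ramp, length(vsel), length(rampIdx),
                                    byrow = TRUE)
    perfused[, postIdx] <- peakAmplitude *
      exp(-outer(kmap, t[postIdx] - tp))
    speckleMask <- NULL
    if (!is.null(speckle) && speckle$n > 0) {
      r <- min(speckle$radius, 2L)
      speckleMask <- matrix(FALSE, H, W)
      cy <- sample(seq(1 + r, H - r), speckle$n, replace = TRUE)
      cx <- sample(seq(1 + r, W - r), speckle$n, replace = TRUE)
      for (i in seq_len(speckle$n)) {
        for (dy in -r:r) for (dx in -r:r) {
          if (dy * dy + dx * dx <= r * r)
            speckleMask[cy[i] + dy, cx[i] + dx] <- TRUE
        }
      }
      ssel <- which(speckleMask)
      scurve <- .bolusCurve(t, speckle$k, arrivalTime, riseTime,
                            peakAmplitude)
      for (k in seq_len(nT)) {
        frame <- matrix(0, H, W)
        frame[ssel] <- scurve[k]
        data[, , k] <- frame
      }
    }
    for (k in seq_len(nT)) {
      frame <- data[, , k]
      frame[vsel] <- pmax(frame[vsel], perfused[, k])
      data[, , k] <- frame
    }
    if (additiveSd > 0) {
      z <- stats::rnorm(length(data))
      z <- pmin(5, pmax(-5, z))
      data <- array(pmax(0, data + additiveSd * z), dim = dim(data))
    }
    new("FrameStack", data = data, fps = fps, pixelSize = scene@pixelSize,
        modality = "contrast",
        meta = list(sceneConfig = scene@config,
                    kinetics = list(arrivalTime = arrivalTime,
                                    riseTime = riseTime,
                                    peakAmplitude = peakAmplitude,
                                    kPerFlow = kPerFlow),
                    noise = list(additiveSd = additiveSd, seed = seed),
                    kMap = kField, speckleMask = speckleMask))
  })
}

#' Render a benchtop tube-flow phantom series
#'
#' Emulates the microfluidic validation: a straight horizontal tube of the
#' given diameter imaged at several known flow velocities. The rendered
#' velocity index is a strictly increasing, saturating function of velocity
#' (\code{v / (v + indexV50)}), modulated and degraded like an SMI
#' recording, so the area-adjusted index over the tube recovers the
#' velocity ranking.
#'
#' @param velocities flow velocities, mm/s (positive, any order).
#' @param tubeDiameter inner diameter, micrometers (benchtop sizes: 408 and
#'   506).
#' @param pixelSize mm per pixel.
#' @param height,width image size, px.
#' @param duration recording length per velocity, s.
#' @param fps frame rate.
#' @param dropout,additiveSd,modAmplitude,modFreq noise model as in
#'   \code{\link{renderNoncontrast}}; set the first three to 0 for a
#'   noiseless phantom.
#' @param indexV50 half-saturation velocity of the index transform, mm/s.
#' @param seed RNG seed (required).
#' @return list of \linkS4class{FrameStack}, one per velocity, with
#'   attributes \code{velocities} and \code{tubeMask}.
#' @export
renderTubePhantom <- function(velocities, tubeDiameter = 408,
                              pixelSize = 0.05, height = 48, width = 96,
                              duration = 15, fps = 39, dropout = 0.1,
                              additiveSd = 0.05, modAmplitude = 0.2,
                              modFreq = 5, indexV50 = 30, seed) {
  if (any(velocities <= 0)) stop("velocities must be positive")
  if (missing(seed)) stop("a seed is required")
  thick <- max(1L, round(tubeDiameter / 1000 / pixelSize))
  mid <- height / 2
  rows <- matrix(seq_len(height), height, width)
  tube <- abs(rows - mid) <= thick / 2
  nFrames <- floor(duration * fps)
  tt <- (seq_len(nFrames) - 1) / fps
  withSeed(seed, {
    stacks <- lapply(velocities, function(v) {
      vi <- v / (v + indexV50)
      phase <- stats::runif(1, 0, 2 * pi)
      mod <- 1 + modAmplitude * sin(2 * pi * modFreq * tt + phase)
      data <- array(0, dim = c(height, width, nFrames))
      tsel <- which(tube)
      nv <- length(tsel)
      for (k in seq_len(nFrames)) {
        val <- rep(vi * mod[k], nv)
        if (dropout > 0) val[stats::runif(nv) < dropout] <- 0
        if (additiveSd > 0)
          val <- pmax(0, val + stats::rnorm(nv, 0, additiveSd))
        frame <- matrix(0, height, width)
        frame[tsel] <- val
        data[, , k] <- frame
      }
      new("FrameStack", data = data, fps = fps, pixelSize = pixelSize,
          modality = "noncontrast",
          meta = list(velocity = v, tubeDiameter = tubeDiameter,
                      indexV50 = indexV50))
    })
    attr(stacks, "velocities") <- velocities
    attr(stacks, "tubeMask") <- tube
    stacks
  })
}

#' Area-adjusted index of each tube-phantom recording
#'
#' Time-averages each stack and computes the area-adjusted index over the
#' tube cross-section, yielding one index per velocity.
#'
#' @param stacks output of \code{\link{renderTubePhantom}}.
#' @param coloredThreshold passed to \code{\link{areaAdjustedIndex}}.
#' @return numeric vector of indices, one per stack.
#' @export
tubePhantomIndices <- function(stacks, coloredThreshold = 0) {
  tube <- attr(stacks, "tubeMask")
  vapply(stacks, function(s) {
    m <- timeAverageMap(s)
    areaAdjustedIndex(m@values[tube], coloredThreshold)
  }, numeric(1))
}
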