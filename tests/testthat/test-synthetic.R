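test_that("scene generation is deterministic and validates its inputs", {
  a <- makeScene(seed = 1)
  b <- makeScene(seed = 1)
  expect_identical(vesselMask(a), vesselMask(b))
  expect_identical(trueFlow(a), trueFlow(b))
  expect_identical(a@geometry@upperBorder, b@geometry@upperBorder)
  d <- makeScene(seed = 2)
  expect_false(identical(vesselMask(a), vesselMask(d)))
  expect_error(makeScene(height = 32, seed = 1), "64")
  expect_error(makeScene(pixelSize = 0, seed = 1), "pixelSize")
  expect_error(makeScene(), "seed")
})

test_that("degenerate truth gives constant flow on vessels", {
  tr <- defaultTruth(umbraDepth = 0, penumbraHeights = c(0, 0))
  sc <- makeScene(truth = tr, seed = 3)
  v <- trueFlow(sc)[vesselMask(sc)]
  expect_equal(v, rep(0.5, length(v)))
  expect_true(all(trueFlow(sc)[!vesselMask(sc)] == 0))
})

test_that("truth profile returns baseline far from injury and obeys shape", {
  tr <- defaultTruth()
  expect_lt(abs(evalTruthProfile(tr, 50) - tr@baselineFlow), 1e-6)
  expect_lt(abs(evalTruthProfile(tr, -50) - tr@baselineFlow), 1e-6)
  tz <- truthZoneLocations(tr)
  expect_lt(tz$rostral, 0)
  expect_gt(tz$caudal, 0)
  expect_true(tz$rostral < tz$umbra && tz$umbra < tz$caudal)
  expect_error(defaultTruth(umbraDepth = 0.6, baselineFlow = 0.5))
  expect_error(defaultTruth(penumbraOffsets = c(1, 2)))
})

test_that("binning vessel-pixel truth recovers the analytic profile", {
  sc <- makeScene(seed = 4)
  g <- injuryGeometry(sc)
  dims <- dim(vesselMask(sc))
  dmap <- signedDistanceMap(g, dims)
  fm <- flowMapOf(trueFlow(sc))
  p <- binProfile(fm, dmap, vesselMask(sc))
  # brute-force oracle: per-pixel evaluation of the analytic profile,
  # grouped by the same half-open bins
  idx <- floor(dmap[vesselMask(sc)] / 0.1 + 1e-7)
  truthMean <- tapply(evalTruthProfile(sceneTruth(sc),
                                       dmap[vesselMask(sc)]), idx, mean)
  got <- indexValues(p)[match(as.numeric(names(truthMean)),
                              floor(binCenters(p) / 0.1 + 1e-7))]
  expect_lt(max(abs(got - truthMean)), 1e-9)
  # and against the analytic value at bin centers, within discretization
  analytic <- evalTruthProfile(sceneTruth(sc), binCenters(p))
  expect_lt(max(abs(indexValues(p) - analytic)), 0.01)
})

test_that("noncontrast render: noise-free frames equal the true flow map", {
  sc <- makeScene(seed = 5)
  st <- renderNoncontrast(sc, nFrames = 4, dropout = 0, additiveSd = 0,
                          modAmplitude = 0, seed = 6)
  for (k in 1:4) expect_equal(frameData(st)[, , k], trueFlow(sc))
  m <- timeAverageMap(st)
  expect_equal(flowValues(m), trueFlow(sc))
})

test_that("cardiac modulation of mean 1 over whole cycles averages out", {
  sc <- makeScene(seed = 7)
  # 40 frames at 40 fps with 5 Hz modulation: exactly 5 cycles
  st <- renderNoncontrast(sc, nFrames = 40, fps = 40, dropout = 0,
                          additiveSd = 0, modAmplitude = 0.3, modFreq = 5,
                          seed = 8)
  m <- timeAverageMap(st)
  expect_lt(max(abs(flowValues(m) - trueFlow(sc))), 1e-9)
})

test_that("off-vessel pixels carry exactly zero in noncontrast stacks", {
  sc <- makeScene(seed = 9)
  st <- renderNoncontrast(sc, nFrames = 6, seed = 10)   # default noise on
  off <- !vesselMask(sc)
  expect_true(all(apply(frameData(st), 3, function(f) all(f[off] == 0))))
})

test_that("render determinism holds for both arms", {
  sc <- makeScene(seed = 11)
  a <- renderNoncontrast(sc, nFrames = 5, seed = 12)
  b <- renderNoncontrast(sc, nFrames = 5, seed = 12)
  expect_identical(frameData(a), frameData(b))
  ca <- renderContrast(sc, duration = 40, fps = 2, seed = 13)
  cb <- renderContrast(sc, duration = 40, fps = 2, seed = 13)
  expect_identical(frameData(ca), frameData(cb))
})

test_that("bolus series follow ramp-then-exponential kinetics exactly", {
  k <- 0.05
  y <- renderBolusSeries(k, fps = 39, duration = 150)
  t <- (seq_along(y) - 1) / 39
  tp <- 15
  expect_true(all(y[t < 8] == 0))
  post <- t >= tp
  # log-linear regression oracle on the clean rendered series
  fitk <- -coef(lm(log(y[post]) ~ I(t[post] - tp)))[[2]]
  expect_lt(abs(fitk - k), 1e-6)
  expect_equal(max(y), 0.5)
  expect_error(renderBolusSeries(0.05, fps = 0), "fps")
  expect_error(renderBolusSeries(0.05, duration = 10, riseTime = 7),
               "twice")
})

test_that("contrast render keeps unperfused pixels below threshold", {
  sc <- makeScene(seed = 14)
  st <- renderContrast(sc, duration = 40, fps = 2, seed = 15)
  perfused <- st@meta$kMap > 0
  offMax <- apply(frameData(st), 3, function(f) max(f[!perfused]))
  expect_lt(max(offMax), 0.015)
})

test_that("speckle blobs are suppressed by the offset-disk opening", {
  sc <- makeScene(seed = 16)
  st <- renderContrast(sc, duration = 60, fps = 4, additiveSd = 0,
                       speckle = list(n = 4, radius = 1, k = 0.3),
                       seed = 17)
  raw <- decayMap(st, latestPeakTime = 55)
  opened <- openOffsetDisk(flowValues(raw))
  spk <- st@meta$speckleMask & !(st@meta$kMap > 0)  # blobs on background
  expect_true(any(spk))
  expect_gt(min(flowValues(raw)[spk]), 0.15)        # artifact present
  expect_lt(max(opened[spk]), 0.1)                  # removed (<= 2 x height)
})

test_that("tube phantom index rises monotonically with velocity", {
  vel <- c(5, 10, 20, 35, 55, 80, 110, 150)
  stacks <- renderTubePhantom(vel, dropout = 0, additiveSd = 0,
                              modAmplitude = 0, seed = 18)
  idx <- tubePhantomIndices(stacks)
  expect_true(all(diff(idx) > 0))
  expect_equal(suppressWarnings(cor(vel, idx, method = "spearman")), 1)
  # diameter enters only via geometry: same expected index
  big <- renderTubePhantom(50, tubeDiameter = 506, dropout = 0,
                           additiveSd = 0, modAmplitude = 0, seed = 19)
  small <- renderTubePhantom(50, tubeDiameter = 408, dropout = 0,
                             additiveSd = 0, modAmplitude = 0, seed = 20)
  expect_equal(tubePhantomIndices(big), tubePhantomIndices(small))
  expect_error(renderTubePhantom(c(-1, 5), seed = 1), "positive")
})
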