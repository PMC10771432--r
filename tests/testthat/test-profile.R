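test_that("signed distances are exact for axis-aligned geometry", {
  g <- verticalGeometry(40, 80, 120)
  d <- signedDistanceMap(g, c(80, 120))
  expect_equal(d[30, 50], +0.5)      # 10 px right of the line at 0.05 mm/px
  expect_equal(d[30, 30], -0.5)
  expect_equal(d[45, 40], 0)         # on the line
})

test_that("signed distances match brute-force point-to-segment search", {
  g <- new("InjuryGeometry",
           injuryLine = rbind(c(30.3, 8.2), c(44.8, 70.6)),  # slanted
           upperBorder = cbind(c(1, 90), c(5, 5)),
           lowerBorder = cbind(c(1, 90), c(72, 72)),
           pixelSize = 0.07)
  d <- signedDistanceMap(g, c(80, 90))
  set.seed(11)
  for (i in 1:100) {
    r <- sample(80, 1); c <- sample(90, 1)
    want <- brutePointSegDist(c, r, c(30.3, 8.2), c(44.8, 70.6)) * 0.07
    expect_lt(abs(abs(d[r, c]) - want), 1e-6)
  }
  expect_error(signedDistanceMap(
    new("InjuryGeometry", injuryLine = rbind(c(10, 10), c(20, 10)),
        upperBorder = cbind(1, 5), lowerBorder = cbind(1, 50),
        pixelSize = 0.05), c(60, 60)), "parallel")
})

test_that("signed distance is invariant to joint translation", {
  g1 <- verticalGeometry(30, 70, 100)
  g2 <- verticalGeometry(45, 70, 100)
  d1 <- signedDistanceMap(g1, c(70, 100))
  d2 <- signedDistanceMap(g2, c(70, 100))
  expect_equal(d1[20:50, 1:80], d2[20:50, 16:95])
})

test_that("the degenerate injury line is rejected", {
  expect_error(new("InjuryGeometry",
                   injuryLine = rbind(c(10, 10), c(10, 10)),
                   upperBorder = cbind(1, 5), lowerBorder = cbind(1, 50),
                   pixelSize = 0.05), "degenerate")
})

test_that("ROI mask is strictly between the borders", {
  g <- verticalGeometry(50, 100, 80, upperRow = 10, lowerRow = 50)
  m <- roiMask(g, c(100, 80))
  expect_true(all(m[11:49, ]))
  expect_false(any(m[c(1:10, 50:100), ]))
  # borders touching at one column: zero-width ROI there
  gt <- new("InjuryGeometry", injuryLine = rbind(c(40, 2), c(40, 79)),
            upperBorder = cbind(c(1, 40, 80), c(10, 40, 10)),
            lowerBorder = cbind(c(1, 80), c(40, 40)),
            pixelSize = 0.05)
  mt <- roiMask(gt, c(80, 80))
  expect_false(any(mt[, 40]))
  expect_true(any(mt[, 1]))
})

test_that("ROI mask matches a per-column scanline oracle", {
  set.seed(12)
  xs <- sort(sample(5:75, 6))
  up <- cbind(xs, runif(6, 5, 25))
  lo <- cbind(xs, runif(6, 40, 70))
  g <- new("InjuryGeometry", injuryLine = rbind(c(40, 2), c(40, 79)),
           upperBorder = up, lowerBorder = lo, pixelSize = 0.05)
  m <- roiMask(g, c(80, 80))
  for (x in seq_len(80)) {
    uy <- approx(up[, 1], up[, 2], x, rule = 2)$y
    ly <- approx(lo[, 1], lo[, 2], x, rule = 2)$y
    expect_identical(m[, x], seq_len(80) > uy & seq_len(80) < ly)
  }
})

test_that("area-adjusted index follows its defining identity", {
  expect_equal(areaAdjustedIndex(c(0, 0, 0, 0)), 0)
  expect_equal(areaAdjustedIndex(c(4, 0, 0, 0)), 1.0)  # v=4, frac=1/4
  expect_true(is.na(areaAdjustedIndex(numeric(0))))
  set.seed(13)
  for (i in 1:20) {
    v <- round(runif(50, 0, 3), 2) * rbinom(50, 1, 0.6)
    expect_lt(abs(areaAdjustedIndex(v) - mean(v)), 1e-12)
  }
  # with a positive threshold the index differs from the plain mean
  v <- c(0.1, 0.5, 2)
  expect_equal(areaAdjustedIndex(v, coloredThreshold = 0.2),
               mean(c(0.5, 2)) * 2 / 3)
})

test_that("binning produces uniform grids and conserves total flow", {
  g <- verticalGeometry(50, 64, 100)
  d <- signedDistanceMap(g, c(64, 100))
  m <- roiMask(g, c(64, 100))
  set.seed(14)
  vals <- matrix(runif(64 * 100) * rbinom(64 * 100, 1, 0.5), 64, 100)
  p <- binProfile(flowMapOf(vals), d, m)
  expect_lt(max(abs(diff(binCenters(p)) - 0.1)), 1e-9)
  # conservation: count-weighted sum of binned I equals total ROI flow
  expect_lt(abs(sum(indexValues(p) * binCounts(p), na.rm = TRUE) -
                sum(vals[m])), 1e-9)
  expect_equal(sum(binCounts(p)), sum(m))
  # uniform flow: every nonempty bin equals the constant
  pu <- binProfile(flowMapOf(matrix(0.7, 64, 100)), d, m)
  expect_true(all(abs(indexValues(pu) - 0.7) < 1e-12))
  expect_error(binProfile(flowMapOf(vals), d, matrix(FALSE, 64, 100)),
               "empty")
})

test_that("shifting the injury line shifts all bin assignments", {
  H <- 64; W <- 100
  set.seed(15)
  vals <- matrix(runif(H * W), H, W)
  g1 <- verticalGeometry(50, H, W)
  g2 <- verticalGeometry(52, H, W)   # 2 px = one 0.1 mm bin at 0.05 mm/px
  m <- roiMask(g1, c(H, W))
  p1 <- binProfile(flowMapOf(vals), signedDistanceMap(g1, c(H, W)), m)
  p2 <- binProfile(flowMapOf(vals), signedDistanceMap(g2, c(H, W)), m)
  i1 <- indexValues(p1); i2 <- indexValues(p2)
  expect_equal(binCenters(p1), binCenters(p2) + 0.1)
  expect_equal(i1, i2)
})

test_that("profile smoothing implements an 11-bin NA-aware average", {
  cent <- seq(-2.05, 2.05, by = 0.1)
  flat <- profileOf(cent, rep(0.4, length(cent)))
  expect_equal(indexValues(smoothProfile(flat)), rep(0.4, length(cent)))
  imp <- rep(0, length(cent)); imp[21] <- 1
  si <- indexValues(smoothProfile(profileOf(cent, imp)))
  expect_equal(si[16:26], rep(1 / 11, 11))
  expect_equal(si[c(15, 27)], c(0, 0))
  set.seed(16)
  y <- runif(length(cent))
  naive <- sapply(seq_along(y), function(i)
    mean(y[max(1, i - 5):min(length(y), i + 5)]))
  expect_lt(max(abs(indexValues(smoothProfile(profileOf(cent, y))) -
                    naive)), 1e-12)
})

test_that("smoothing excludes missing bins and limits support growth", {
  cent <- seq(0.05, 4.05, by = 0.1)
  y <- rep(NA_real_, length(cent))
  y[15:20] <- 1
  s <- indexValues(smoothProfile(profileOf(cent, y)))
  expect_true(all(is.finite(s[10:25])))
  expect_true(all(is.na(s[c(1:9, 26:41)])))   # at most half a window out
  expect_equal(s[15:20], rep(1, 6))
})

test_that("noiseless scene profiles track the analytic truth", {
  sc <- makeScene(seed = 23)
  st <- renderNoncontrast(sc, nFrames = 3, dropout = 0, additiveSd = 0,
                          modAmplitude = 0, seed = 24)
  p <- flowProfile(timeAverageMap(st), injuryGeometry(sc))
  # vessel-fraction scaling cancels in shape: correlation with truth ~ 1
  tv <- evalTruthProfile(sceneTruth(sc), binCenters(p))
  keep <- is.finite(indexValues(p))
  expect_gt(cor(indexValues(p)[keep], tv[keep]), 0.97)
})
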