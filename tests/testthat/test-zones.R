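bumpProfile <- function(centers, base = 0.2, dip = 0.15, dipSd = 0.4,
                        bumps = c(-1, 1), height = 0.25, sd = 0.3) {
  y <- rep(base, length(centers)) -
    dip * exp(-centers^2 / (2 * dipSd^2))
  for (b in bumps) y <- y + height * exp(-(centers - b)^2 / (2 * sd^2))
  profileOf(centers, y)
}

test_that("penumbra peaks are found at the nearest prominent maxima", {
  cent <- seq(-3, 3, by = 0.1)
  p <- bumpProfile(cent)
  pk <- findPenumbraPeaks(p)
  expect_true(pk$labelingOk)
  expect_equal(unname(pk$rostral["location"]), -1)
  expect_equal(unname(pk$caudal["location"]), 1)
  expect_gt(unname(pk$rostral["prominence"]), 0.2)
  flat <- profileOf(cent, rep(0.3, length(cent)))
  expect_false(findPenumbraPeaks(flat)$labelingOk)
  expect_error(findPenumbraPeaks(profileOf(seq(0.05, 2, 0.1),
                                           runif(20))), "both sides")
})

test_that("with several peaks per side the closest to 0 mm wins", {
  cent <- seq(-4, 4, by = 0.1)
  p <- bumpProfile(cent, bumps = c(-2.5, -1.5, -0.6, 0.6, 1.5, 2.5),
                   height = 0.2, sd = 0.15)
  pk <- findPenumbraPeaks(p)
  expect_equal(unname(pk$rostral["location"]), -0.6)
  expect_equal(unname(pk$caudal["location"]), 0.6)
  expect_gte(nrow(pk$peaks), 6)
})

test_that("peak prominences equal the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(50:500, 1)
    y <- abs(cumsum(rnorm(n, 0, 0.05))) + runif(n, 0, 1e-4) + 0.2
    cent <- seq(-n / 20, by = 0.1, length.out = n)
    pk <- findPenumbraPeaks(profileOf(cent, y), minProminence = 0)
    want <- brutePeaks(y)
    expect_equal(pk$peaks$location, cent[want$idx])
    expect_equal(pk$peaks$prominence, want$prom, tolerance = 1e-12)
  }
})

test_that("umbra localization applies the tie rules", {
  cent <- seq(-2, 2, by = 0.1)
  # unique V-shaped minimum off-center
  yv <- 0.5 + abs(cent + 0.2)
  um <- locateUmbra(profileOf(cent, yv), -1.5, 1.5)
  expect_equal(um$location, -0.2)
  # plateau minimum over 0.0-0.4 mm reports the plateau center
  yp <- rep(0.6, length(cent))
  yp[cent > -0.05 & cent < 0.45] <- 0.1
  up <- locateUmbra(profileOf(cent, yp), -1.5, 1.5)
  expect_equal(up$location, 0.2)
  expect_match(paste(up$note, collapse = " "), "plateau")
  # non-consecutive ties break toward 0 mm
  yn <- rep(0.6, length(cent))
  yn[which.min(abs(cent + 1.0))] <- 0.1
  yn[which.min(abs(cent - 0.4))] <- 0.1
  un <- locateUmbra(profileOf(cent, yn), -1.5, 1.5)
  expect_equal(un$location, 0.4)
  # strictly monotone segment: endpoint minimum, flagged
  ym <- 0.2 + 0.3 * (cent + 2)
  umon <- locateUmbra(profileOf(cent, ym), -1.5, 1.5)
  expect_equal(umon$location, -1.4)
  expect_match(paste(umon$note, collapse = " "), "monotone")
})

test_that("half-maximum extent matches closed-form geometry", {
  cent <- seq(-2, 2, by = 0.1)
  # symmetric triangle: crossings at half the flank -> extent 1.0
  ytri <- pmin(1, pmax(0, abs(cent)))
  et <- halfMaxExtent(profileOf(cent, ytri), 0, 0,
                      c(rostral = -1, caudal = 1),
                      c(rostral = 1, caudal = 1))
  expect_equal(et$extent, 1.0)
  expect_equal(unname(et$crossings), c(-0.5, 0.5))
  # asymmetric flanks: rostral slope 2 (peak at -0.5), caudal slope 1
  yas <- ifelse(cent < 0, pmin(1, -2 * cent), pmin(1, cent))
  ea <- halfMaxExtent(profileOf(cent, yas), 0, 0,
                      c(rostral = -0.5, caudal = 1),
                      c(rostral = 1, caudal = 1))
  expect_equal(ea$extent, 0.25 + 0.5)
  # Gaussian dip: extent equals the closed-form FWHM within one bin
  sigma <- 0.6
  yg <- 1 - 0.8 * exp(-cent^2 / (2 * sigma^2))
  eg <- halfMaxExtent(profileOf(cent, yg), 0, min(yg),
                      c(rostral = -1.9, caudal = 1.9),
                      c(rostral = 1, caudal = 1))
  fwhm <- 2 * sigma * sqrt(2 * log(2))
  expect_lt(abs(eg$extent - fwhm), 0.1)
})

test_that("distal means cover exactly the bins beyond the penumbras", {
  cent <- seq(-3, 3, by = 0.1)
  yb <- rep(0.5, length(cent))
  expect_equal(distalFlows(profileOf(cent, yb),
                           c(rostral = -1, caudal = 1)),
               c(rostral = 0.5, caudal = 0.5))
  # linear trend: closed-form mean over each distal span
  yl <- 0.5 + 0.1 * cent
  dl <- distalFlows(profileOf(cent, yl), c(rostral = -1, caudal = 1))
  expect_equal(unname(dl["rostral"]), mean(yl[cent < -1]))
  expect_equal(unname(dl["caudal"]), mean(yl[cent > 1]))
  # penumbra at the edge: that side is missing, not zero
  de <- distalFlows(profileOf(cent, yb), c(rostral = -3, caudal = 1))
  expect_true(is.na(de["rostral"]))
  expect_false(is.na(de["caudal"]))
})

test_that("full labeling composes the pieces coherently", {
  cent <- seq(-3, 3, by = 0.1)
  p <- bumpProfile(cent)
  zl <- labelZones(p)
  expect_true(labelingOk(zl))
  expect_true(zl@penumbraLocation["rostral"] < zl@umbraLocation)
  expect_true(zl@umbraLocation < zl@penumbraLocation["caudal"])
  expect_true(all(zl@penumbraProminence >= 0))
  expect_gt(injuryExtent(zl), 0)
  row <- zoneTable(zl)
  expect_equal(nrow(row), 1L)
  expect_true(row$labeling_ok)
  flat <- labelZones(profileOf(cent, rep(0.3, length(cent))))
  expect_false(labelingOk(flat))
  expect_match(flat@notes[1], "no qualifying peak")
})

test_that("prominence is shift-invariant and extent scale-invariant", {
  cent <- seq(-3, 3, by = 0.1)
  p <- bumpProfile(cent)
  z1 <- labelZones(p)
  z2 <- labelZones(profileOf(cent, indexValues(p) + 0.3))
  expect_equal(z1@penumbraProminence, z2@penumbraProminence)
  expect_equal(z1@umbraLocation, z2@umbraLocation)
  z3 <- labelZones(profileOf(cent, indexValues(p) * 2.5))
  expect_equal(z1@injuryExtent, z3@injuryExtent)
  expect_equal(z1@halfMaxPoints, z3@halfMaxPoints)
})

test_that("pre-injury parameters are read at post-injury locations", {
  cent <- seq(-3, 3, by = 0.1)
  post <- bumpProfile(cent)
  zl <- labelZones(post)
  same <- preInjuryParameters(post, zl)
  expect_equal(same@umbraFlow, zl@umbraFlow)
  expect_equal(same@penumbraFlow, zl@penumbraFlow)
  expect_equal(same@distalFlow, zl@distalFlow)
  pre <- profileOf(cent, rep(0.42, length(cent)))
  flat <- preInjuryParameters(pre, zl)
  expect_equal(unname(flat@umbraFlow), 0.42)
  expect_equal(unname(flat@penumbraFlow),
               c(0.42, 0.42), ignore_attr = TRUE)
  expect_equal(unname(flat@penumbraProminence), c(0, 0),
               ignore_attr = TRUE)
  # manual index-lookup oracle on a random pre profile
  set.seed(32)
  yr <- runif(length(cent), 0.2, 0.8)
  prer <- profileOf(cent, yr)
  got <- preInjuryParameters(prer, zl)
  expect_equal(unname(got@umbraFlow),
               yr[which.min(abs(cent - zl@umbraLocation))])
  expect_equal(unname(got@penumbraFlow["caudal"]),
               yr[which.min(abs(cent - zl@penumbraLocation["caudal"]))])
  # grid mismatch is an error
  off <- profileOf(cent + 40, yr)
  expect_error(preInjuryParameters(off, zl), "grid")
})
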