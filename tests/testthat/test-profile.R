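roiOf <- function(m, pitch = 0.07) {
  new("ROISegment", pixels = m, pitchMm = pitch, widthPx = ncol(m),
      heightPx = nrow(m), topRow = 1L, colRange = c(1L, ncol(m)))
}

test_that("profile is the per-row mean, matching a brute-force summation", {
  expect_equal(profileValues(computeProfile(roiOf(rbind(c(1, 3), c(5, 7))))),
               c(2, 6))
  expect_equal(profileValues(computeProfile(roiOf(matrix(7, 10, 4)))),
               rep(7, 10))
  set.seed(21)
  m <- matrix(runif(29 * 114, 0, 255), 114, 29)
  brute <- numeric(114)
  for (i in 1:114) {
    s <- 0
    for (j in 1:29) s <- s + m[i, j]
    brute[i] <- s / 29
  }
  expect_equal(profileValues(computeProfile(roiOf(m))), brute,
               tolerance = 1e-12)
})

test_that("normalize-and-cut divides by the max and starts there", {
  p <- normalizeAndCut(qusbone:::boneProfile(c(2, 4, 8, 6, 4), 0.07))
  expect_equal(profileValues(p), c(1, 0.75, 0.5))
  expect_true(p@normalized && p@cutApplied)
  # already cut: only scaling
  q <- normalizeAndCut(qusbone:::boneProfile(c(10, 6, 2), 0.07))
  expect_equal(profileValues(q), c(1, 0.6, 0.2))
  # tie at the maximum keeps the first (shallowest) occurrence
  t <- normalizeAndCut(qusbone:::boneProfile(c(3, 5, 5, 1), 0.07))
  expect_equal(profileValues(t), c(1, 1, 0.2))
  expect_error(normalizeAndCut(qusbone:::boneProfile(c(0, 0), 0.07)),
               "all-zero")
})

test_that("resampling interpolates linearly onto the reference grid", {
  idp <- qusbone:::boneProfile(c(1, 0.5, 0.25), 0.07, TRUE, TRUE)
  expect_equal(profileValues(resampleProfile(idp)), c(1, 0.5, 0.25))
  mid <- qusbone:::boneProfile(c(1, 0), 0.14, TRUE, TRUE)
  expect_equal(profileValues(resampleProfile(mid)), c(1, 0.5, 0))
  # monotone nonincreasing in -> monotone nonincreasing out
  set.seed(8)
  for (i in 1:20) {
    v <- rev(sort(runif(30))); v <- v / max(v)
    pitch <- runif(1, 0.05, 0.12)
    out <- profileValues(resampleProfile(
      qusbone:::boneProfile(v, pitch, TRUE, TRUE)))
    expect_true(all(diff(out) <= 1e-12))
    expect_equal(out[1], 1)
  }
  short <- qusbone:::boneProfile(c(1, 0.9), 0.03, TRUE, TRUE)
  expect_error(resampleProfile(short), "shorter than one reference step")
})

test_that("truncation keeps the first 25 samples and flags short profiles", {
  v <- seq(1, 0.4, length.out = 30)
  p30 <- qusbone:::boneProfile(v / max(v), 0.07, TRUE, TRUE)
  expect_equal(profileValues(truncateProfile(p30)), v[1:25])
  p25 <- truncateProfile(p30)
  expect_equal(profileValues(truncateProfile(p25)), profileValues(p25))
  p24 <- qusbone:::boneProfile(v[1:24], 0.07, TRUE, TRUE)
  expect_error(truncateProfile(p24), "too short")
})

test_that("level means follow the 5 x 5 partition", {
  flat <- qusbone:::boneProfile(rep(1, 25), 0.07, TRUE, TRUE)
  lv <- profileLevelMeans(flat)
  expect_equal(lv$levelMeans, rep(1, 5))
  expect_equal(lv$levelAll, 1)
  tri <- qusbone:::boneProfile((24:0) / 24, 0.07, TRUE, TRUE)
  lvt <- profileLevelMeans(tri)
  expect_equal(lvt$levelMeans, c(22, 17, 12, 7, 2) / 24)
  expect_equal(lvt$levelAll, 0.5)
  expect_equal(lvt$levelAll, mean(lvt$levelMeans))
  short <- qusbone:::boneProfile(rep(1, 24), 0.07, TRUE, TRUE)
  expect_error(profileLevelMeans(short), "uniform levels")
})

test_that("intensity slope is the least-squares slope over the first 10 samples", {
  lin <- qusbone:::boneProfile(1 - 0.007 * (0:24), 0.07, TRUE, TRUE)
  expect_equal(profileSlope(lin), -0.1, tolerance = 1e-12)
  flat <- qusbone:::boneProfile(rep(1, 25), 0.07, TRUE, TRUE)
  expect_equal(profileSlope(flat), 0)
  set.seed(4)
  for (i in 1:20) {
    v <- c(1, runif(9))  # max at the cut origin, as the chain guarantees
    p <- qusbone:::boneProfile(v, 0.07, TRUE, TRUE)
    d <- (0:9) * 0.07
    expect_equal(profileSlope(p), bruteSlope(d, v), tolerance = 1e-12)
  }
})

test_that("the whole chain is invariant to a positive gain factor", {
  sim <- makePhantom(0.5, speckleCv = 0.3, seed = 77)
  roi <- selectROI(sim$image, sim$annotation)
  s1 <- summarizeROI(roi, "SULC")
  roi2 <- roiOf(pixels(roi) * 0.37, pitchMm(roi))
  s2 <- summarizeROI(roi2, "SULC")
  expect_equal(levelValues(s1), levelValues(s2), tolerance = 1e-12)
  expect_equal(overallMean(s1), overallMean(s2), tolerance = 1e-12)
  expect_equal(intensitySlope(s1), intensitySlope(s2), tolerance = 1e-12)
})

test_that("noise-free phantom profiles match the exponential closed form", {
  for (depth in c(31, 41)) {
    p <- phantomParams(0.3, imageDepthMm = depth, speckleCv = 0)
    sim <- simulateImage(p, "SULC")
    roi <- selectROI(sim$image, sim$annotation)
    prof <- chainProfile(roi)
    oracle <- exp(-p$decayPerMm * (0:24) * 0.07)
    expect_lt(max(abs(profileValues(prof) - oracle)), 0.02)
  }
})

test_that("femoral average is the arithmetic site mean with missing sites dropped", {
  mk <- function(lv, slope, site) new("DepthLevelSummary",
    levelMeans = lv, levelAll = mean(lv), slope = slope, site = site,
    nSites = 1L)
  a <- mk(c(0.9, 0.3, 0.2, 0.15, 0.1), -1.2, "MED")
  fb3 <- femoralAverage(list(a, a, a))
  expect_equal(levelValues(fb3), levelValues(a))
  expect_equal(intensitySlope(fb3), -1.2)
  expect_identical(siteLabel(fb3), "FB")
  b <- mk(c(0.8, 0.6, 0.4, 0.3, 0.2), -0.6, "SULC")
  fb2 <- femoralAverage(list(a, b, NULL))
  expect_equal(levelValues(fb2)[2], (0.3 + 0.6) / 2)
  expect_equal(intensitySlope(fb2), -0.9)
  expect_equal(fb2@nSites, 2L)
  expect_error(femoralAverage(list()), "no site summaries")
})
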