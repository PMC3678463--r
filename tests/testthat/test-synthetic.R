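test_that("noise-free column profile equals the closed form at band center", {
  p <- phantomParams(0.4, speckleCv = 0)
  sim <- makePhantom(0.4, speckleCv = 0)
  img <- pixels(sim$image)
  pitch <- pitchMm(sim$image)
  cc <- sim$annotation@centerCol
  ifaceRow <- sim$annotation@points[sim$annotation@points[, "col"] == cc, "row"]
  depths <- (0:30) * pitch
  expected <- round(255 * p$interfacePeak * exp(-p$decayPerMm * depths))
  expect_equal(img[ifaceRow + 0:30, cc], unname(expected))
})

test_that("identical seed and parameters give bit-identical images", {
  a <- makePhantom(0.6, speckleCv = 0.3, seed = 42)
  b <- makePhantom(0.6, speckleCv = 0.3, seed = 42)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$annotation@points, b$annotation@points)
  c <- makePhantom(0.6, speckleCv = 0.3, seed = 43)
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("sub-interface intensity is monotone in severity at fixed depth", {
  # closed form: higher severity -> brighter interface, flatter decay
  for (depthMm in c(0.2, 0.5, 1.0)) {
    vals <- sapply(seq(0, 1, by = 0.1), function(s)
      phantomIntensity(depthMm, phantomParams(s, speckleCv = 0)))
    expect_true(all(diff(vals) > 0))
  }
  # pixel check at 0.5 mm below the interface, severity 0.9 vs 0.1
  hi <- makePhantom(0.9, speckleCv = 0); lo <- makePhantom(0.1, speckleCv = 0)
  off <- round(0.5 / pitchMm(hi$image))
  cc <- hi$annotation@centerCol
  rowAt <- function(sim) sim$annotation@points[
    sim$annotation@points[, "col"] == cc, "row"]
  expect_gt(pixels(hi$image)[rowAt(hi) + off, cc],
            pixels(lo$image)[rowAt(lo) + off, cc])
  # analytic slope magnitude is nonincreasing in severity
  slopes <- sapply(seq(0, 1, by = 0.25), function(s)
    phantomParams(s)$decayPerMm)
  expect_true(all(diff(slopes) < 0))
})

test_that("simulateImage validates site and raster size", {
  p <- phantomParams(0.5)
  expect_error(simulateImage(p, "TIB"), "invalid site")
  tiny <- phantomParams(0.5, rows = 100L, imageDepthMm = 31)
  expect_error(simulateImage(tiny, "MED"), "8 mm ROI")
  narrow <- phantomParams(0.5, cols = 20L)
  expect_error(simulateImage(narrow, "MED"), "2 mm ROI")
})

test_that("deterministic grade assignment hits the scale extremes", {
  r0 <- assignGrades(0, noiseSdKl = 0, noiseSdNoyes = 0)
  expect_equal(r0@klGrade, 0)
  expect_equal(unname(r0@noyesNumeric), c(0, 0, 0))
  expect_equal(r0@fas1, 0); expect_equal(r0@fas2, 0)
  r1 <- assignGrades(1, noiseSdKl = 0, noiseSdNoyes = 0)
  expect_equal(r1@klGrade, 4)
  expect_equal(unname(r1@noyesNumeric), c(6, 6, 6))
  expect_equal(r1@fas1, 18); expect_equal(r1@fas2, 3)
})

test_that("noisy grades stay in range and track severity", {
  set.seed(202)
  sev <- runif(200)
  kl <- numeric(200); f1 <- numeric(200)
  for (i in 1:200) {
    r <- assignGrades(sev[i])
    expect_true(r@klGrade %in% 0:4)
    expect_true(all(r@noyesNumeric %in% 0:6))
    expect_true(r@fas1 >= 0 && r@fas1 <= 18)
    kl[i] <- r@klGrade; f1[i] <- r@fas1
  }
  expect_gt(spearmanCorrelation(sev, kl)$r, 0.5)
  expect_gt(spearmanCorrelation(sev, f1)$r, 0.5)
})

test_that("cohort writing is deterministic and complete", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- cohortConfig(seed = 9)
  m1 <- writeCohort(2, d1, cfg)
  m2 <- writeCohort(2, d2, cfg)
  expect_identical(m1, m2)
  expect_lte(nrow(m1), 6)
  expect_setequal(unique(m1$subject_id), c("S001", "S002"))
  # bytes identical across the two runs
  for (f in file.path(m1$image_path)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # every present image has a matching annotation
  expect_true(all(file.exists(file.path(d1, m1$annotation_path))))
  expect_true(file.exists(file.path(d1, "grades.csv")))
})

test_that("a missing-site probability of one removes exactly that site", {
  d <- withr::local_tempdir()
  m <- writeCohort(3, d, cohortConfig(seed = 5, missingSiteProb = 0))
  expect_setequal(unique(m$site), c("MED", "SULC", "LAT"))
  d2 <- withr::local_tempdir()
  m2 <- writeCohort(3, d2, cohortConfig(
    seed = 5, missingSiteProb = c(MED = 0, SULC = 0, LAT = 1)))
  expect_setequal(unique(m2$site), c("MED", "SULC"))
  expect_equal(nrow(m2), 6)
})
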