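test_that("Spearman correlation handles monotone transforms, reversals and ties", {
  expect_equal(spearmanCorrelation(1:10, (1:10)^2)$r, 1)
  expect_equal(spearmanCorrelation(1:4, 4:1)$r, -1)
  res <- spearmanCorrelation(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(res$r, bruteSpearman(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  # cross-check against the independent reference implementation
  ref <- suppressWarnings(cor.test(c(1, 2, 2, 4), c(1, 3, 2, 4),
                                   method = "spearman"))
  expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(12); y <- sample(0:4, 12, replace = TRUE)
    if (var(y) == 0) next
    r0 <- spearmanCorrelation(x, y)$r
    expect_equal(spearmanCorrelation(exp(3 * x), y)$r, r0, tolerance = 1e-12)
    expect_equal(spearmanCorrelation(x, 10 * y + 2)$r, r0, tolerance = 1e-12)
  }
})

test_that("Spearman drops missing pairs and enforces preconditions", {
  x <- c(1, 2, NA, 4, 5, 6); y <- c(2, NA, 3, 5, 4, 6)
  res <- spearmanCorrelation(x, y)
  expect_equal(res$n, 4)
  expect_error(spearmanCorrelation(c(1, 2, NA, NA), c(1, 2, 3, 4)),
               "at least 4")
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "zero variance")
})

test_that("exact permutation p agrees with enumeration and t approx is sane", {
  set.seed(7)
  x <- rnorm(6); y <- rnorm(6)
  pex <- spearmanCorrelation(x, y, pMethod = "exact")$p
  expect_true(pex >= 0 && pex <= 1)
  # perfectly concordant small sample: exact p = 2/n! (both extreme tails)
  expect_equal(spearmanCorrelation(1:5, 1:5, pMethod = "exact")$p,
               2 / factorial(5), tolerance = 1e-12)
  expect_error(spearmanCorrelation(1:9, 9:1, pMethod = "exact"), "n <= 8")
})

test_that("Fisher r-to-Z interval round-trips and behaves in n and r", {
  ci <- fisherCI(0.5, 20)
  hw <- qnorm(0.975) / sqrt(17)
  expect_equal(atanh(ci), atanh(0.5) + c(-hw, hw), tolerance = 1e-12)
  expect_equal(fisherCI(0, 25), -rev(fisherCI(0, 25)))  # symmetric about 0
  # contains r; width strictly decreasing in n
  for (r in c(-0.7, 0.1, 0.6)) {
    w <- sapply(c(10, 20, 40, 80), function(n) diff(fisherCI(r, n)))
    expect_true(all(diff(w) < 0))
    ci <- fisherCI(r, 15)
    expect_true(ci[1] <= r && r <= ci[2])
  }
  expect_error(fisherCI(1, 10), "degenerate")
  expect_error(fisherCI(0.5, 3), "at least 4")
})

test_that("pooled t comparison matches the closed-form statistic", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- twoSampleT(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$tStat, tHand, tolerance = 1e-12)
  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$tStat, 0)
  expect_equal(same$p, 1)
  welch <- twoSampleT(rnorm(10), rnorm(10, sd = 5), equalVariance = FALSE)
  expect_true(is.finite(welch$p))
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})

test_that("correlation table reports r, CI, p and stars per pair", {
  set.seed(3)
  d <- data.frame(v1 = 1:20 + rnorm(20, sd = 2),
                  g1 = rep(0:4, each = 4),
                  gAllNA = NA_real_)
  tb <- correlationTable(d, data.frame(variable = c("v1", "v1"),
                                       grading = c("g1", "gAllNA")))
  expect_equal(nrow(tb), 2)
  expect_true(tb$r[1] > 0.5)
  expect_true(tb$ci_low[1] <= tb$r[1] && tb$r[1] <= tb$ci_high[1])
  expect_equal(tb$stars[1], significanceStars(tb$p[1]))
  expect_true(is.na(tb$r[2]))  # degenerate pair flagged, no crash
  expect_error(correlationTable(d, d[0, c(1, 2)]), "at least one")
})

test_that("star thresholds follow the table footnote convention", {
  expect_equal(significanceStars(c(0.0005, 0.005, 0.04, 0.2, NA)),
               c("***", "**", "*", "", NA))
})
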