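# shared fixtures built in code

# noise-free phantom image + annotation at given severity/depth/site
makePhantom <- function(severity = 0.5, imageDepthMm = 31, site = "SULC",
                        speckleCv = 0, seed = NA_integer_, ...) {
  simulateImage(phantomParams(severity, imageDepthMm = imageDepthMm,
                              speckleCv = speckleCv, seed = seed, ...),
                site)
}

# run the full profile chain on an ROI, returning the 25-sample profile
chainProfile <- function(roi, referencePitchMm = 0.07, nSamples = 25L) {
  truncateProfile(resampleProfile(normalizeAndCut(computeProfile(roi)),
                                  referencePitchMm), nSamples)
}

# independent midrank computation: rank by counting, averaging ties
bruteMidranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

# independent Spearman r: product-moment on brute-force midranks, sum formulas
bruteSpearman <- function(x, y) {
  rx <- bruteMidranks(x); ry <- bruteMidranks(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  num <- n * sum(rx * ry) - sx * sy
  den <- sqrt((n * sum(rx^2) - sx^2) * (n * sum(ry^2) - sy^2))
  num / den
}

# independent OLS slope via the normal equations
bruteSlope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}
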