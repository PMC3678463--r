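#' Compute the raw bone intensity profile of an ROI
#'
#' The depth-ordered profile is the arithmetic mean gray level of each
#' horizontal ROI row, shallow to deep.
#'
#' @param roi an [ROISegment-class].
#' @return An unnormalized [BoneProfile-class] of length `heightPx`.
#' @export
computeProfile <- function(roi) {
  px <- pixels(roi)
  if (!length(px)) stop("empty ROI")
  boneProfile(rowMeans(px), pitchMm(roi))
}

#' Normalize a profile to its maximum and cut it to start there
#'
#' Dividing by the global maximum removes overall gain differences between
#' acquisitions; cutting the vector to start at the maximum anchors depth 0
#' on the specular interface reflection. Ties at the maximum keep the first
#' (shallowest) occurrence, preserving the deepest extent of the profile.
#'
#' @param profile a [BoneProfile-class].
#' @return A normalized, cut [BoneProfile-class] with `values[1] == 1`.
#' @examples
#' p <- normalizeAndCut(qusbone:::boneProfile(c(2, 4, 8, 6, 4), 0.07))
#' profileValues(p)  # 1.00 0.75 0.50
#' @export
normalizeAndCut <- function(profile) {
  v <- profile@values
  m <- max(v)
  if (m <= 0) stop("cannot normalize an all-zero profile")
  v <- v / m
  iMax <- which.max(v)  # first occurrence on ties
  boneProfile(v[iMax:length(v)], profile@pitchMm, normalized = TRUE,
              cutApplied = TRUE)
}

#' Resample a profile onto the reference pixel pitch
#'
#' Imaging depth settings of 31 and 41 mm give different pixel sizes; a
#' linear interpolation onto the 31 mm reference pitch (~0.07 mm) makes
#' profiles comparable across subjects. The output grid shares the input's
#' origin (depth 0 at the cut maximum, so `values[1] == 1` is preserved) and
#' never extrapolates beyond the last native sample.
#'
#' @param profile a cut, normalized [BoneProfile-class].
#' @param referencePitchMm target sample spacing, mm.
#' @return A [BoneProfile-class] at the reference pitch.
#' @export
resampleProfile <- function(profile, referencePitchMm = 0.07) {
  if (!profile@normalized || !profile@cutApplied)
    stop("resampleProfile expects a normalized, cut profile")
  v <- profile@values
  nativeDepth <- (seq_along(v) - 1) * profile@pitchMm
  extent <- nativeDepth[length(v)]
  if (extent < referencePitchMm)
    stop("profile extent (", signif(extent, 3),
         " mm) is shorter than one reference step")
  outDepth <- seq(0, extent, by = referencePitchMm)
  out <- stats::approx(nativeDepth, v, xout = outDepth)$y
  out <- out / max(out)  # guards rounding; max is at depth 0 already
  boneProfile(out, referencePitchMm, normalized = TRUE, cutApplied = TRUE)
}

#' Truncate a profile to its analysis length
#'
#' The resampled profile is reduced to its first `nSamples` samples
#' (25 samples, ~1.74 mm, at the 0.07 mm reference pitch). A profile too
#' short to truncate raises an error so callers can drop the site and
#' continue.
#'
#' @param profile a [BoneProfile-class].
#' @param nSamples samples to retain.
#' @return The truncated [BoneProfile-class].
#' @export
truncateProfile <- function(profile, nSamples = 25L) {
  v <- profile@values
  if (length(v) < nSamples)
    stop("profile too short to truncate: ", length(v), " < ", nSamples,
         " samples")
  boneProfile(v[seq_len(nSamples)], profile@pitchMm,
              normalized = profile@normalized,
              cutApplied = profile@cutApplied)
}

#' Depth-level means of a 25-sample profile
#'
#' Divides the truncated profile into 5 consecutive uniform levels of 5
#' samples (each ~0.35 mm at the reference pitch; level 2 spans
#' 0.35--0.70 mm) and returns the level means plus the overall mean.
#'
#' @param profile a cut, normalized 25-sample [BoneProfile-class].
#' @param nLevels number of uniform levels.
#' @return list with `levelMeans` (numeric(5)) and `levelAll`.
#' @export
profileLevelMeans <- function(profile, nLevels = 5L) {
  v <- profile@values
  if (!profile@normalized || !profile@cutApplied)
    stop("profileLevelMeans expects a normalized, cut profile")
  if (length(v) %% nLevels != 0)
    stop("profile length ", length(v), " is not divisible into ", nLevels,
         " uniform levels")
  per <- length(v) %/% nLevels
  lm5 <- vapply(seq_len(nLevels),
                function(k) mean(v[((k - 1) * per + 1):(k * per)]),
                numeric(1))
  list(levelMeans = lm5, levelAll = mean(v))
}

#' Intensity slope over the first two depth levels
#'
#' Ordinary least-squares slope of normalized intensity against physical
#' depth (mm) over the first `nSamples` samples (10 samples, ~0.7 mm, at
#' the reference pitch) — the shallow region where attenuation keeps the
#' signal-to-noise ratio usable. A decaying profile has a negative slope;
#' sclerosis flattens it toward zero.
#'
#' @param profile a cut, normalized [BoneProfile-class] of length >= 10.
#' @param nSamples samples in the fit window.
#' @return slope in normalized intensity per mm.
#' @export
profileSlope <- function(profile, nSamples = 10L) {
  v <- profile@values
  if (!profile@normalized || !profile@cutApplied)
    stop("profileSlope expects a normalized, cut profile")
  if (length(v) < nSamples)
    stop("profile has fewer than ", nSamples, " samples")
  depth <- (seq_len(nSamples) - 1) * profile@pitchMm
  unname(stats::coef(stats::lm(v[seq_len(nSamples)] ~ depth))[2L])
}

#' Full profile chain for one ROI
#'
#' Runs the analysis chain in its fixed order — row means, normalize, cut
#' at the maximum, resample to the reference pitch, truncate to 25
#' samples — and summarises the result into depth-level means, overall mean
#' and intensity slope.
#'
#' @param roi an [ROISegment-class].
#' @param site site label stored in the summary.
#' @param referencePitchMm reference pitch, mm.
#' @param profileSamples truncation length (divisible by 5).
#' @param slopeSamples slope fit window (<= `profileSamples`).
#' @return A [DepthLevelSummary-class] for the site.
#' @export
summarizeROI <- function(roi, site, referencePitchMm = 0.07,
                         profileSamples = 25L, slopeSamples = 10L) {
  prof <- computeProfile(roi)
  prof <- normalizeAndCut(prof)
  prof <- resampleProfile(prof, referencePitchMm)
  prof <- truncateProfile(prof, profileSamples)
  lv <- profileLevelMeans(prof)
  new("DepthLevelSummary", levelMeans = lv$levelMeans, levelAll = lv$levelAll,
      slope = profileSlope(prof, slopeSamples), site = site, nSites = 1L)
}

#' Average site summaries into the femoral summary
#'
#' The per-subject femoral value (site label `"FB"`) of every field — the
#' five level means, the overall mean and the slope — is the arithmetic mean
#' over the sites available for that subject; missing sites are simply
#' omitted and the contributing count recorded.
#'
#' @param summaries list of per-site [DepthLevelSummary-class] objects.
#' @return A [DepthLevelSummary-class] with site `"FB"`.
#' @export
femoralAverage <- function(summaries) {
  summaries <- Filter(Negate(is.null), summaries)
  if (!length(summaries))
    stop("no site summaries available for this subject")
  lm5 <- rowMeans(vapply(summaries, levelValues, numeric(5)))
  new("DepthLevelSummary",
      levelMeans = lm5,
      levelAll = mean(vapply(summaries, overallMean, numeric(1))),
      slope = mean(vapply(summaries, intensitySlope, numeric(1))),
      site = "FB", nSites = length(summaries))
}
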