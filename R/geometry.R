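#' Convert a physical length to pixels
#'
#' Rounds half away from zero, which reproduces the standard ROI pixel
#' counts: a 2 mm ROI width is 29 px at the 31 mm-depth pitch (0.0700 mm)
#' and 22 px at the 41 mm-depth pitch (0.0909 mm).
#'
#' @param mm length in mm (nonnegative).
#' @param pitchMm pixel pitch in mm.
#' @return integer pixel count.
#' @examples
#' mmToPx(2, 31 / 443)  # 29
#' mmToPx(2, 41 / 451)  # 22
#' @export
mmToPx <- function(mm, pitchMm) {
  stopifnot(mm >= 0, pitchMm > 0)
  as.integer(floor(mm / pitchMm + 0.5))
}

#' Default raster height for an imaging depth
#'
#' The two depth settings used in suprapatellar knee scanning map to rasters
#' whose pitch reproduces the published per-ROI pixel counts: 31 mm -> 443
#' rows (pitch ~0.0700 mm), 41 mm -> 451 rows (pitch ~0.0909 mm).
#'
#' @param imageDepthMm 31 or 41.
#' @return integer row count.
#' @export
defaultRows <- function(imageDepthMm) {
  if (imageDepthMm == 31) return(443L)
  if (imageDepthMm == 41) return(451L)
  stop("imageDepthMm must be 31 or 41 (got ", imageDepthMm,
       "); pass rows explicitly for other depths")
}

#' Physical depth span of a profile depth level
#'
#' The truncated 25-sample profile is divided into 5 consecutive uniform
#' levels of 5 samples each; level k spans depths
#' `(k-1)*5*pitch` to `k*5*pitch` below the reflection maximum.
#'
#' @param level level index 1--5.
#' @param pitchMm sample pitch, default the 0.07 mm reference.
#' @param samplesPerLevel samples per level (5).
#' @return numeric(2): start and end depth in mm.
#' @examples
#' levelDepthRange(2)  # 0.35 0.70
#' @export
levelDepthRange <- function(level, pitchMm = 0.07, samplesPerLevel = 5L) {
  stopifnot(level %in% 1:5)
  c((level - 1L) * samplesPerLevel, level * samplesPerLevel) * pitchMm
}

#' Physical span of the intensity-slope fit window
#'
#' @param nSamples samples in the fit window (10 = first two levels).
#' @param pitchMm sample pitch in mm.
#' @return window span in mm (0.7 at defaults).
#' @export
slopeWindowMm <- function(nSamples = 10L, pitchMm = 0.07) {
  nSamples * pitchMm
}
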