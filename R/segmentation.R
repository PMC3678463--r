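#' Select the rectangular subchondral-bone ROI
#'
#' Reproduces the semiautomatic segmentation step: the operator traces a
#' border line along the cartilage-bone interface where it is perpendicular
#' to the beam, and the rectangular ROI is then selected automatically —
#' 2 mm wide, centered laterally on the annotation's center column, and
#' 8 mm tall starting a small guard margin above the annotated interface
#' row (so the reflection maximum always falls inside; the profile is later
#' cut at that maximum, making the exact top placement immaterial).
#'
#' Width and height in pixels depend only on the pixel pitch, never on
#' image content: 29 x 114 px at the 31 mm-depth raster and 22 x 88 px at
#' 41 mm.
#'
#' @param image a [BModeImage-class].
#' @param annotation an [InterfaceAnnotation-class]; the interface row at
#'   the center column is interpolated linearly from the traced points if
#'   not annotated exactly there.
#' @param roiWidthMm,roiHeightMm ROI extent in mm (defaults 2 and 8).
#' @param guardPx guard margin above the annotated interface row, px.
#' @return An [ROISegment-class].
#' @export
selectROI <- function(image, annotation, roiWidthMm = 2, roiHeightMm = 8,
                      guardPx = 3L) {
  px <- pixels(image)
  pts <- annotation@points
  if (any(pts[, "row"] > nrow(px)) || any(pts[, "col"] > ncol(px)))
    stop("annotation points fall outside the image")
  cc <- annotation@centerCol
  if (cc < min(pts[, "col"]) || cc > max(pts[, "col"]))
    stop("centerCol lies outside the annotated column span")
  pitch <- pitchMm(image)
  widthPx <- mmToPx(roiWidthMm, pitch)
  heightPx <- mmToPx(roiHeightMm, pitch)

  ifaceRow <- round(stats::approx(pts[, "col"], pts[, "row"], xout = cc)$y)
  topRow <- as.integer(ifaceRow - guardPx)
  left <- as.integer(cc - (widthPx - 1L) %/% 2L)
  right <- left + widthPx - 1L
  bottom <- topRow + heightPx - 1L
  if (topRow < 1L)
    stop("ROI exceeds image bounds on the top side (row ", topRow, ")")
  if (bottom > nrow(px))
    stop("ROI exceeds image bounds on the bottom side (row ", bottom,
         " > ", nrow(px), ")")
  if (left < 1L)
    stop("ROI exceeds image bounds on the left side (column ", left, ")")
  if (right > ncol(px))
    stop("ROI exceeds image bounds on the right side (column ", right,
         " > ", ncol(px), ")")
  new("ROISegment", pixels = px[topRow:bottom, left:right, drop = FALSE],
      pitchMm = pitch, widthPx = widthPx, heightPx = heightPx,
      topRow = topRow, colRange = c(left, right))
}

#' Automatic interface detection (convenience extension)
#'
#' The reference workflow places the interface line manually; this helper
#' recovers it automatically on well-behaved images by locating, per column,
#' the brightest pixel below a minimum depth. Columns whose peak does not
#' exceed `threshold` (fraction of the 8-bit full scale) are reported as
#' failures; if no column passes, detection fails outright.
#'
#' @param image a [BModeImage-class].
#' @param colWindow integer pair: first and last column to scan.
#' @param minDepthMm ignore rows shallower than this depth (skips near-field
#'   clutter).
#' @param threshold minimum peak gray level as a fraction of 255.
#' @return An [InterfaceAnnotation-class] over the columns that passed;
#'   failed columns are attached as attribute `"failedCols"`. `centerCol` is
#'   the passing column with the strongest peak.
#' @export
autoInterface <- function(image, colWindow, minDepthMm = 2, threshold = 0.25) {
  px <- pixels(image)
  stopifnot(length(colWindow) == 2, colWindow[1] >= 1,
            colWindow[2] <= ncol(px), colWindow[1] < colWindow[2])
  minRow <- max(1L, mmToPx(minDepthMm, pitchMm(image)))
  cols <- colWindow[1]:colWindow[2]
  sub <- px[minRow:nrow(px), cols, drop = FALSE]
  peakIdx <- apply(sub, 2L, which.max)
  peakVal <- sub[cbind(peakIdx, seq_along(cols))]
  ok <- peakVal >= threshold * 255
  if (!any(ok))
    stop("interface detection failed: no column peak reaches ",
         threshold * 255, " gray levels in columns ", colWindow[1], "..",
         colWindow[2])
  ann <- interfaceAnnotation(
    data.frame(row = peakIdx[ok] + minRow - 1L, col = cols[ok]),
    centerCol = cols[ok][which.max(peakVal[ok])])
  attr(ann, "failedCols") <- cols[!ok]
  ann
}
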