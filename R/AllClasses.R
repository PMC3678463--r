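#' @import methods
NULL

#' Femoral imaging sites
#'
#' The three femoral locations scanned in the transverse suprapatellar view:
#' medial condyle (`MED`), intercondylar notch / sulcus (`SULC`) and lateral
#' condyle (`LAT`).
#'
#' @export
SITES <- c("MED", "SULC", "LAT")

#' B-mode ultrasound image
#'
#' A single-frame grayscale B-mode image. Rows index depth (axial direction,
#' shallow to deep), columns index the lateral direction. Pixels are assumed
#' square with pitch `imageDepthMm / nrow(pixels)`.
#'
#' @slot pixels numeric matrix of nonnegative gray levels (0--255).
#' @slot imageDepthMm physical imaging depth of the frame, mm.
#' @slot pitchMm pixel pitch, mm (axial = lateral).
#' @slot site one of `MED`, `SULC`, `LAT`.
#' @slot subjectId subject identifier.
#' @export
setClass("BModeImage",
  slots = c(
    pixels       = "matrix",
    imageDepthMm = "numeric",
    pitchMm      = "numeric",
    site         = "character",
    subjectId    = "character"
  )
)

setValidity("BModeImage", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px) || any(!is.finite(px)))
    msg <- c(msg, "pixels must be a finite numeric matrix")
  else if (any(px < 0))
    msg <- c(msg, "pixels must be nonnegative")
  if (length(object@pitchMm) != 1L || object@pitchMm <= 0)
    msg <- c(msg, "pitchMm must be a single positive number")
  else if (abs(nrow(px) * object@pitchMm - object@imageDepthMm) >
             object@pitchMm)
    msg <- c(msg, "rows * pitchMm must equal imageDepthMm to within one pitch")
  if (!object@site %in% SITES)
    msg <- c(msg, sprintf("site must be one of %s", paste(SITES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a B-mode image object
#'
#' @param pixels numeric matrix of gray levels, rows = depth.
#' @param imageDepthMm physical imaging depth in mm.
#' @param site site label (`MED`, `SULC`, `LAT`).
#' @param subjectId subject identifier.
#' @param pitchMm pixel pitch in mm; defaults to `imageDepthMm / nrow(pixels)`.
#' @return A [BModeImage-class] object.
#' @examples
#' img <- bModeImage(matrix(0, 443, 380), imageDepthMm = 31, site = "MED")
#' pitchMm(img)
#' @export
bModeImage <- function(pixels, imageDepthMm, site, subjectId = "",
                       pitchMm = imageDepthMm / nrow(pixels)) {
  new("BModeImage", pixels = pixels, imageDepthMm = imageDepthMm,
      pitchMm = pitchMm, site = site, subjectId = subjectId)
}

#' Cartilage-bone interface annotation
#'
#' An ordered trace of the cartilage-bone interface in pixel coordinates,
#' together with the column at which the beam is locally perpendicular to the
#' interface (where the specular reflection is strongest and the ROI is
#' centered).
#'
#' @slot points two-column matrix (`row`, `col`) with strictly increasing
#'   columns.
#' @slot centerCol column on which the ROI is centered.
#' @export
setClass("InterfaceAnnotation",
  slots = c(points = "matrix", centerCol = "numeric")
)

setValidity("InterfaceAnnotation", function(object) {
  p <- object@points
  msg <- character()
  if (ncol(p) != 2L || nrow(p) < 2L)
    msg <- c(msg, "points must be an n x 2 (row, col) matrix with n >= 2")
  else {
    if (any(diff(p[, 2L]) <= 0))
      msg <- c(msg, "point columns must be strictly increasing")
    if (any(p < 1))
      msg <- c(msg, "point coordinates must be >= 1")
  }
  if (length(object@centerCol) != 1L)
    msg <- c(msg, "centerCol must be a single column index")
  if (length(msg)) msg else TRUE
})

#' Construct an interface annotation
#'
#' @param points two-column matrix or data.frame with columns `row`, `col`.
#' @param centerCol column where the beam is perpendicular to the interface;
#'   defaults to the median annotated column.
#' @return An [InterfaceAnnotation-class] object.
#' @export
interfaceAnnotation <- function(points, centerCol = NULL) {
  points <- as.matrix(points[, c("row", "col")])
  storage.mode(points) <- "double"
  if (is.null(centerCol))
    centerCol <- points[ceiling(nrow(points) / 2), "col"]
  new("InterfaceAnnotation", points = points, centerCol = as.numeric(centerCol))
}

#' Rectangular region of interest below the cartilage-bone interface
#'
#' @slot pixels the extracted sub-matrix, rows = depth.
#' @slot pitchMm pixel pitch in mm.
#' @slot widthPx ROI width in pixels (2 mm at the native pitch).
#' @slot heightPx ROI height in pixels (8 mm at the native pitch).
#' @slot topRow first (shallowest) source-image row of the ROI.
#' @slot colRange first and last source-image columns of the ROI.
#' @export
setClass("ROISegment",
  slots = c(
    pixels   = "matrix",
    pitchMm  = "numeric",
    widthPx  = "integer",
    heightPx = "integer",
    topRow   = "integer",
    colRange = "integer"
  )
)

setValidity("ROISegment", function(object) {
  msg <- character()
  if (ncol(object@pixels) != object@widthPx)
    msg <- c(msg, "widthPx must equal ncol(pixels)")
  if (nrow(object@pixels) != object@heightPx)
    msg <- c(msg, "heightPx must equal nrow(pixels)")
  if (object@pitchMm <= 0)
    msg <- c(msg, "pitchMm must be positive")
  if (length(msg)) msg else TRUE
})

#' Depth-ordered bone intensity profile
#'
#' Mean gray level per ROI row, ordered from shallow to deep. Flags record
#' whether the profile has been normalized to its maximum and cut to start
#' there.
#'
#' @slot values mean gray-level per depth sample (index 1 = shallowest).
#' @slot pitchMm sample spacing in mm.
#' @slot normalized `TRUE` once divided by the profile maximum.
#' @slot cutApplied `TRUE` once the profile starts at its maximum.
#' @export
setClass("BoneProfile",
  slots = c(
    values     = "numeric",
    pitchMm    = "numeric",
    normalized = "logical",
    cutApplied = "logical"
  )
)

setValidity("BoneProfile", function(object) {
  v <- object@values
  msg <- character()
  if (!length(v) || any(!is.finite(v)))
    msg <- c(msg, "values must be a nonempty finite numeric vector")
  if (object@pitchMm <= 0)
    msg <- c(msg, "pitchMm must be positive")
  if (isTRUE(object@normalized) && length(v)) {
    if (abs(max(v) - 1) > 1e-8 || any(v < -1e-12))
      msg <- c(msg, "normalized profile must lie in [0, 1] with max 1")
    if (isTRUE(object@cutApplied) && abs(v[1L] - 1) > 1e-8)
      msg <- c(msg, "cut profile must start at its maximum (value 1)")
  }
  if (length(msg)) msg else TRUE
})

boneProfile <- function(values, pitchMm, normalized = FALSE,
                        cutApplied = FALSE) {
  new("BoneProfile", values = as.numeric(values), pitchMm = pitchMm,
      normalized = normalized, cutApplied = cutApplied)
}

#' Depth-level summary of a bone profile
#'
#' The five uniform depth-level means of a 25-sample normalized profile, the
#' overall mean, and the least-squares intensity slope over the first two
#' levels. `site` is a femoral site label or `"FB"` for the per-subject
#' femoral average; `nSites` records how many sites contributed (1 for a
#' single-site summary).
#'
#' @slot levelMeans numeric(5), means of samples 1--5, 6--10, ..., 21--25.
#' @slot levelAll mean of all 25 samples.
#' @slot slope intensity slope over the first 10 samples, normalized
#'   intensity per mm.
#' @slot site site label or `"FB"`.
#' @slot nSites number of contributing sites.
#' @export
setClass("DepthLevelSummary",
  slots = c(
    levelMeans = "numeric",
    levelAll   = "numeric",
    slope      = "numeric",
    site       = "character",
    nSites     = "integer"
  )
)

setValidity("DepthLevelSummary", function(object) {
  msg <- character()
  if (length(object@levelMeans) != 5L)
    msg <- c(msg, "levelMeans must have length 5")
  else if (abs(object@levelAll - mean(object@levelMeans)) > 1e-8)
    msg <- c(msg, "levelAll must equal the mean of the 5 level means")
  if (!object@site %in% c(SITES, "FB"))
    msg <- c(msg, "site must be MED, SULC, LAT or FB")
  if (length(msg)) msg else TRUE
})

#' Per-subject grade record
#'
#' Radiographic Kellgren-Lawrence grade, per-site numeric Noyes grades and
#' the derived composite femoral arthroscopic scores; `severity` carries the
#' latent osteoarthritis burden for synthetic subjects (NA for clinical data).
#'
#' @slot subjectId subject identifier.
#' @slot klGrade K-L grade 0--4, or NA.
#' @slot noyesNumeric named numeric(3) (`MED`, `SULC`, `LAT`), each 0--6 or NA.
#' @slot fas1 sum of the three Noyes numerics, 0--18, NA if any site missing.
#' @slot fas2 binned FAS1 (0; 1--6; 7--12; 13--18 -> 0..3), NA with fas1.
#' @slot severity latent severity in \[0, 1\], NA unless synthetic.
#' @export
setClass("SubjectRecord",
  slots = c(
    subjectId    = "character",
    klGrade      = "numeric",
    noyesNumeric = "numeric",
    fas1         = "numeric",
    fas2         = "numeric",
    severity     = "numeric"
  )
)

setValidity("SubjectRecord", function(object) {
  msg <- character()
  kl <- object@klGrade
  if (!is.na(kl) && (kl < 0 || kl > 4 || kl != round(kl)))
    msg <- c(msg, "klGrade must be an integer in 0..4 or NA")
  ny <- object@noyesNumeric
  if (length(ny) != 3L || !all(SITES %in% names(ny)))
    msg <- c(msg, "noyesNumeric must be named MED, SULC, LAT")
  else if (any(!is.na(ny) & (ny < 0 | ny > 6 | ny != round(ny))))
    msg <- c(msg, "noyesNumeric values must be integers in 0..6 or NA")
  if (!is.na(object@fas1) && (object@fas1 < 0 || object@fas1 > 18))
    msg <- c(msg, "fas1 must lie in 0..18 or be NA")
  if (!is.na(object@fas2) && !object@fas2 %in% 0:3)
    msg <- c(msg, "fas2 must lie in 0..3 or be NA")
  if (!is.na(object@severity) &&
      (object@severity < 0 || object@severity > 1))
    msg <- c(msg, "severity must lie in [0, 1] or be NA")
  if (length(msg)) msg else TRUE
})

#' Construct a subject grade record
#'
#' FAS1 and FAS2 are derived from the Noyes numerics unless all three sites
#' are present is false, in which case they are NA.
#'
#' @param subjectId subject identifier.
#' @param klGrade K-L grade 0--4 or NA.
#' @param noyesNumeric numeric(3) named `MED`, `SULC`, `LAT` (0--6 or NA).
#' @param severity latent severity (synthetic cohorts only).
#' @return A [SubjectRecord-class] object with `fas1`/`fas2` filled in.
#' @export
subjectRecord <- function(subjectId, klGrade = NA_real_,
                          noyesNumeric = c(MED = NA_real_, SULC = NA_real_,
                                           LAT = NA_real_),
                          severity = NA_real_) {
  noyesNumeric <- noyesNumeric[SITES]
  names(noyesNumeric) <- SITES
  f1 <- fas1Score(noyesNumeric)
  f2 <- if (is.na(f1)) NA_real_ else fas2Score(f1)
  new("SubjectRecord", subjectId = as.character(subjectId),
      klGrade = as.numeric(klGrade), noyesNumeric = as.numeric2(noyesNumeric),
      fas1 = as.numeric(f1), fas2 = as.numeric(f2),
      severity = as.numeric(severity))
}

# as.numeric that keeps names
as.numeric2 <- function(x) {
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

setMethod("show", "BModeImage", function(object) {
  cat(sprintf("BModeImage: %d x %d px, depth %.0f mm (pitch %.4f mm), site %s, subject '%s'\n",
              nrow(object@pixels), ncol(object@pixels), object@imageDepthMm,
              object@pitchMm, object@site, object@subjectId))
})

setMethod("show", "BoneProfile", function(object) {
  cat(sprintf("BoneProfile: %d samples, pitch %.4f mm, normalized=%s, cut=%s\n",
              length(object@values), object@pitchMm, object@normalized,
              object@cutApplied))
})

setMethod("show", "DepthLevelSummary", function(object) {
  cat(sprintf("DepthLevelSummary [%s, %d site(s)]\n", object@site,
              object@nSites))
  cat(sprintf("  levels 1-5: %s\n",
              paste(sprintf("%.3f", object@levelMeans), collapse = " ")))
  cat(sprintf("  level all: %.3f   slope: %.3f /mm\n", object@levelAll,
              object@slope))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s': K-L=%s, Noyes(MED,SULC,LAT)=%s, FAS1=%s, FAS2=%s\n",
              object@subjectId, format(object@klGrade),
              paste(format(object@noyesNumeric), collapse = ","),
              format(object@fas1), format(object@fas2)))
})
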