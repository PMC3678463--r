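#' Parameters for a synthetic B-mode subchondral bone phantom
#'
#' Describes one simulated image: a bright, gently parabolic cartilage-bone
#' interface band over an exponentially decaying subchondral bone echo, under
#' multiplicative speckle. A single latent severity in \[0, 1\] drives the
#' physically motivated trends of osteoarthritis: the interface reflection
#' brightens (sclerosis raises the acoustic-impedance step), the
#' sub-interface decay flattens, and the interface thickens from a line into
#' a band.
#'
#' Default severity links (monotone direction is the modelled physics; the
#' coefficients are the generator's calibration):
#' `interfacePeak = 0.5 + 0.5 * severity`,
#' `decayPerMm = 2.0 - 1.2 * severity`,
#' `bandHalfwidthMm = 0.1 + 0.2 * severity`.
#'
#' @param severity latent osteoarthritis burden in \[0, 1\].
#' @param imageDepthMm imaging depth, 31 or 41 mm.
#' @param rows raster height; defaults to [defaultRows()] for the depth.
#' @param cols raster width in pixels.
#' @param interfacePeak peak interface reflectivity in (0, 1].
#' @param decayPerMm exponential intensity decay below the interface, per mm.
#' @param bandHalfwidthMm half-width of the interface band, mm.
#' @param speckleCv coefficient of variation of the multiplicative
#'   unit-mean gamma speckle (0 disables noise).
#' @param curvature parabolic interface bow, px per px^2; `NULL` picks a
#'   site-specific default in [simulateImage()] (sulcus flatter than the
#'   condyles).
#' @param apexDepthMm depth of the interface apex below the transducer, mm.
#' @param cartilageLevel baseline echo level of the cartilage above the
#'   interface, as a fraction of full scale.
#' @param seed integer seed for the speckle; NA draws from the current RNG
#'   stream.
#' @return validated list of class `PhantomParams`.
#' @export
phantomParams <- function(severity,
                          imageDepthMm = 31,
                          rows = defaultRows(imageDepthMm),
                          cols = 380L,
                          interfacePeak = 0.5 + 0.5 * severity,
                          decayPerMm = 2.0 - 1.2 * severity,
                          bandHalfwidthMm = 0.1 + 0.2 * severity,
                          speckleCv = 0.3,
                          curvature = NULL,
                          apexDepthMm = 15,
                          cartilageLevel = 0.05,
                          seed = NA_integer_) {
  p <- list(severity = severity, imageDepthMm = imageDepthMm,
            rows = as.integer(rows), cols = as.integer(cols),
            interfacePeak = interfacePeak, decayPerMm = decayPerMm,
            bandHalfwidthMm = bandHalfwidthMm, speckleCv = speckleCv,
            curvature = curvature, apexDepthMm = apexDepthMm,
            cartilageLevel = cartilageLevel, seed = seed)
  class(p) <- "PhantomParams"
  validatePhantomParams(p)
  p
}

validatePhantomParams <- function(p) {
  stopifnot(
    "severity must lie in [0, 1]" = p$severity >= 0 && p$severity <= 1,
    "interfacePeak must lie in (0, 1]" =
      p$interfacePeak > 0 && p$interfacePeak <= 1,
    "decayPerMm must be positive" = p$decayPerMm > 0,
    "bandHalfwidthMm must be positive" = p$bandHalfwidthMm > 0,
    "speckleCv must be nonnegative" = p$speckleCv >= 0,
    "rows and cols must be positive" = p$rows > 0 && p$cols > 0,
    "cartilageLevel must lie in [0, interfacePeak)" =
      p$cartilageLevel >= 0 && p$cartilageLevel < p$interfacePeak
  )
  invisible(p)
}

# site-specific interface bow: condyles curved, sulcus nearly flat;
# cosmetic only — small enough that the 2 mm ROI stays on-axis
siteCurvature <- function(site) {
  switch(site, MED = 1e-3, LAT = 1e-3, SULC = 2.5e-4,
         stop("invalid site label: ", site))
}

#' Noise-free phantom intensity at a signed depth from the interface
#'
#' The analytic column model: below the interface (`deltaMm >= 0`) the echo
#' is `interfacePeak * exp(-decayPerMm * deltaMm)`; above it, a Gaussian
#' shoulder of the interface band (sd = `bandHalfwidthMm / 2`) decays to the
#' cartilage baseline. The unique maximum sits exactly on the interface.
#'
#' @param deltaMm signed depth from the interface in mm (positive = deeper).
#' @param params a `PhantomParams` object.
#' @return intensity fraction of full scale, vectorized over `deltaMm`.
#' @export
phantomIntensity <- function(deltaMm, params) {
  sigma <- params$bandHalfwidthMm / 2
  below <- params$interfacePeak * exp(-params$decayPerMm * pmax(deltaMm, 0))
  above <- params$cartilageLevel + (params$interfacePeak - params$cartilageLevel) *
    exp(-0.5 * (pmin(deltaMm, 0) / sigma)^2)
  ifelse(deltaMm >= 0, below, above)
}

#' Simulate one B-mode image of a femoral site
#'
#' Renders the analytic phantom of [phantomIntensity()] on the raster, with
#' the interface following a parabola whose apex sits at `apexDepthMm` under
#' the image center, multiplies by i.i.d. unit-mean gamma speckle
#' (shape `1/cv^2`) when `speckleCv > 0`, and quantizes to 8-bit gray
#' levels. The returned annotation traces the interface over the central
#' 2 mm of columns, the region a sonographer would mark where the beam is
#' perpendicular to the bone.
#'
#' @param params a `PhantomParams` object.
#' @param site site label (`MED`, `SULC`, `LAT`); sets the default curvature.
#' @param subjectId subject identifier stored in the image.
#' @return list with elements `image` ([BModeImage-class]) and `annotation`
#'   ([InterfaceAnnotation-class]).
#' @examples
#' sim <- simulateImage(phantomParams(0.5, speckleCv = 0, seed = 1), "SULC")
#' sim$image
#' @export
simulateImage <- function(params, site, subjectId = "synthetic") {
  validatePhantomParams(params)
  if (!site %in% SITES)
    stop("invalid site label: ", site)
  rows <- params$rows; cols <- params$cols
  pitch <- params$imageDepthMm / rows
  curvature <- if (is.null(params$curvature)) siteCurvature(site) else
    params$curvature
  centerCol <- ceiling(cols / 2)
  # interface apex anchored to the raster row nearest the nominal depth,
  # so the analytic profile is sampled exactly on the pixel grid
  apexRow <- round(params$apexDepthMm / pitch)
  ifaceRow <- apexRow + curvature * (seq_len(cols) - centerCol)^2

  guard <- 3L
  heightPx <- mmToPx(8, pitch)
  if (max(ifaceRow) - guard + heightPx > rows)
    stop("raster too small: an 8 mm ROI below the interface at depth ",
         params$apexDepthMm, " mm does not fit in ", rows, " rows")
  if (cols < mmToPx(2, pitch))
    stop("raster too narrow for a 2 mm ROI (", cols, " columns)")

  # deltaMm[r, c]: signed mm from the interface curve
  deltaMm <- (matrix(seq_len(rows), rows, cols) -
              matrix(ifaceRow, rows, cols, byrow = TRUE)) * pitch
  img <- phantomIntensity(deltaMm, params)
  if (params$speckleCv > 0) {
    if (!is.na(params$seed)) set.seed(params$seed)
    shape <- 1 / params$speckleCv^2
    img <- img * stats::rgamma(length(img), shape = shape, rate = shape)
  }
  gray <- matrix(round(255 * pmin(img, 1)), rows, cols)

  halfw <- mmToPx(2, pitch) %/% 2L
  annCols <- (centerCol - halfw):(centerCol + halfw)
  ann <- interfaceAnnotation(
    data.frame(row = round(ifaceRow[annCols]), col = annCols),
    centerCol = centerCol)
  list(image = bModeImage(gray, params$imageDepthMm, site, subjectId,
                          pitchMm = pitch),
       annotation = ann)
}

#' Assign severity-linked ordinal grades to a synthetic subject
#'
#' The latent severity is mapped linearly onto each ordinal scale and
#' perturbed with Gaussian noise before rounding and clamping:
#' K-L = clamp(round(4 s + e), 0, 4) and, per site,
#' Noyes = clamp(round(6 s + e'), 0, 6). FAS1/FAS2 are then derived from the
#' Noyes numerics. With both noise scales 0 the mapping is deterministic
#' (severity 1 gives K-L 4, all Noyes 6, FAS1 18, FAS2 3).
#'
#' @param severity latent severity in \[0, 1\].
#' @param subjectId subject identifier.
#' @param noiseSdKl,noiseSdNoyes Gaussian noise sd on the K-L (0--4) and
#'   Noyes (0--6) scales.
#' @param seed integer seed; NA draws from the current RNG stream.
#' @return A [SubjectRecord-class].
#' @export
assignGrades <- function(severity, subjectId = "synthetic",
                         noiseSdKl = 0.7, noiseSdNoyes = 1.0,
                         seed = NA_integer_) {
  stopifnot(severity >= 0, severity <= 1)
  if (!is.na(seed)) set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  kl <- clamp(round(4 * severity + stats::rnorm(1, 0, noiseSdKl)), 0, 4)
  noyes <- clamp(round(6 * severity + stats::rnorm(3, 0, noiseSdNoyes)), 0, 6)
  names(noyes) <- SITES
  subjectRecord(subjectId, klGrade = kl, noyesNumeric = noyes,
                severity = severity)
}

#' Default configuration for a synthetic cohort
#'
#' The defaults emulate the study conditions the pipeline targets: ~40
#' subjects, imaging depth drawn between 31 and 41 mm, a small per-site
#' image dropout (the per-site n of 38 against 39 subjects), and roughly a
#' fifth of subjects lacking a radiographic K-L grade (31 of 39 radiographed).
#'
#' @param seed master seed for the cohort.
#' @param missingSiteProb probability a site's image is absent; either a
#'   single value for all sites or a named vector over `MED`, `SULC`, `LAT`.
#' @param klMissingProb probability the K-L grade is missing.
#' @param imageDepthsMm candidate imaging depths.
#' @param depthProb sampling probabilities for `imageDepthsMm`.
#' @param speckleCv speckle coefficient of variation.
#' @param noiseSdKl,noiseSdNoyes grade-noise scales, see [assignGrades()].
#' @param severityRange severities are drawn uniformly on this interval.
#' @return named list of class `CohortConfig`.
#' @export
cohortConfig <- function(seed = 1L, missingSiteProb = 0.05,
                         klMissingProb = 0.2,
                         imageDepthsMm = c(31, 41),
                         depthProb = c(0.5, 0.5),
                         speckleCv = 0.3,
                         noiseSdKl = 0.7, noiseSdNoyes = 1.0,
                         severityRange = c(0, 1)) {
  if (length(missingSiteProb) == 1L) {
    missingSiteProb <- rep(missingSiteProb, 3L)
    names(missingSiteProb) <- SITES
  } else if (!all(SITES %in% names(missingSiteProb)))
    stop("missingSiteProb must be scalar or named over MED, SULC, LAT")
  missingSiteProb <- missingSiteProb[SITES]
  stopifnot(all(missingSiteProb >= 0), all(missingSiteProb <= 1),
            klMissingProb >= 0, klMissingProb <= 1,
            length(imageDepthsMm) == length(depthProb),
            all(depthProb >= 0), sum(depthProb) > 0,
            length(severityRange) == 2,
            severityRange[1] >= 0, severityRange[2] <= 1,
            severityRange[1] <= severityRange[2])
  structure(list(seed = as.integer(seed), missingSiteProb = missingSiteProb,
                 klMissingProb = klMissingProb, imageDepthsMm = imageDepthsMm,
                 depthProb = depthProb, speckleCv = speckleCv,
                 noiseSdKl = noiseSdKl, noiseSdNoyes = noiseSdNoyes,
                 severityRange = severityRange),
            class = "CohortConfig")
}

#' Generate and write a synthetic cohort to disk
#'
#' Draws per-subject severities, simulates up to three site images per
#' subject as 8-bit grayscale PNGs with a CSV metadata sidecar, writes
#' per-image interface annotations, a grade table and a manifest. The whole
#' cohort is a deterministic function of `config$seed`.
#'
#' Files written under `outDir`:
#' `images/<subject>_<site>.png`, `annotations/<subject>_<site>.csv`
#' (columns subject_id, site, row, col, is_center), `images_meta.csv`
#' (subject_id, site, image_depth_mm, rows, cols), `grades.csv`,
#' `manifest.csv` and `cohort_config.json`.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param outDir output directory (created if absent).
#' @param config a [cohortConfig()] list.
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(nSubjects, outDir, config = cohortConfig()) {
  if (nSubjects < 1) stop("nSubjects must be at least 1")
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "annotations"), showWarnings = FALSE)
  set.seed(config$seed)

  manifest <- list(); meta <- list(); grades <- list()
  for (i in seq_len(nSubjects)) {
    sid <- sprintf("S%03d", i)
    sev <- stats::runif(1, config$severityRange[1], config$severityRange[2])
    depth <- sample(config$imageDepthsMm, 1,
                    prob = config$depthProb / sum(config$depthProb))
    rec <- assignGrades(sev, sid, config$noiseSdKl, config$noiseSdNoyes)
    klMissing <- stats::runif(1) < config$klMissingProb
    present <- stats::runif(3) >= config$missingSiteProb[SITES]
    names(present) <- SITES

    grades[[i]] <- data.frame(
      subject_id = sid,
      kl_grade = if (klMissing) NA_real_ else rec@klGrade,
      noyes_MED = rec@noyesNumeric[["MED"]],
      noyes_SULC = rec@noyesNumeric[["SULC"]],
      noyes_LAT = rec@noyesNumeric[["LAT"]],
      severity = sev)

    for (site in SITES[present]) {
      sim <- simulateImage(
        phantomParams(sev, imageDepthMm = depth,
                      speckleCv = config$speckleCv),
        site, subjectId = sid)
      imgPath <- file.path("images", sprintf("%s_%s.png", sid, site))
      annPath <- file.path("annotations", sprintf("%s_%s.csv", sid, site))
      png::writePNG(pixels(sim$image) / 255, file.path(outDir, imgPath))
      pts <- sim$annotation@points
      utils::write.csv(
        data.frame(subject_id = sid, site = site,
                   row = pts[, "row"], col = pts[, "col"],
                   is_center = as.integer(pts[, "col"] ==
                                          sim$annotation@centerCol)),
        file.path(outDir, annPath), row.names = FALSE)
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sid, site = site, image_depth_mm = depth,
        rows = nrow(pixels(sim$image)), cols = ncol(pixels(sim$image)))
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = sid, site = site,
        kl_grade = if (klMissing) NA_real_ else rec@klGrade,
        noyes_label = names(which(
          c("0" = 0, "1A" = 1, "1B" = 2, "2A" = 3, "2B" = 4, "3A" = 5,
            "3B" = 6) == rec@noyesNumeric[[site]]))[1],
        noyes_numeric = rec@noyesNumeric[[site]],
        severity = sev, image_path = imgPath, annotation_path = annPath)
    }
  }
  emptyManifest <- data.frame(subject_id = character(), site = character(),
                              kl_grade = numeric(), noyes_label = character(),
                              noyes_numeric = numeric(), severity = numeric(),
                              image_path = character(),
                              annotation_path = character())
  manifest <- if (length(manifest)) do.call(rbind, manifest) else emptyManifest
  if (!length(meta))
    meta <- list(data.frame(subject_id = character(), site = character(),
                            image_depth_mm = numeric(), rows = integer(),
                            cols = integer()))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, meta), file.path(outDir, "images_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, grades), file.path(outDir, "grades.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(outDir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
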