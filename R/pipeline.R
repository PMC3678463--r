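#' Pipeline configuration
#'
#' Bundles every tunable of the simulate/analyze pipeline with its default:
#' the 0.07 mm reference pitch, the 2 x 8 mm ROI, the 25-sample profile,
#' the 10-sample slope window and the 95% confidence level.
#'
#' @param inputDir cohort directory (images, annotations, grades).
#' @param outDir directory for analysis outputs.
#' @param referencePitchMm reference pixel pitch, mm.
#' @param roiWidthMm,roiHeightMm ROI extent, mm.
#' @param profileSamples truncated profile length (divisible by 5).
#' @param slopeSamples slope window length (<= `profileSamples`).
#' @param ciLevel confidence level for Fisher intervals.
#' @param seed master seed (drives simulation only; analysis is
#'   deterministic).
#' @param nSubjects cohort size for [runSimulate()].
#' @param cohort a [cohortConfig()]; defaults to one seeded with `seed`.
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(inputDir = NULL, outDir = NULL,
                           referencePitchMm = 0.07,
                           roiWidthMm = 2, roiHeightMm = 8,
                           profileSamples = 25L, slopeSamples = 10L,
                           ciLevel = 0.95, seed = 1L, nSubjects = 40L,
                           cohort = cohortConfig(seed = seed)) {
  stopifnot("profileSamples must be divisible by 5 (uniform levels)" =
              profileSamples %% 5 == 0,
            "slopeSamples must not exceed profileSamples" =
              slopeSamples <= profileSamples,
            ciLevel > 0, ciLevel < 1)
  structure(list(inputDir = inputDir, outDir = outDir,
                 referencePitchMm = referencePitchMm,
                 roiWidthMm = roiWidthMm, roiHeightMm = roiHeightMm,
                 profileSamples = as.integer(profileSamples),
                 slopeSamples = as.integer(slopeSamples),
                 ciLevel = ciLevel, seed = as.integer(seed),
                 nSubjects = as.integer(nSubjects), cohort = cohort),
            class = "PipelineConfig")
}

#' Simulate a cohort to disk
#'
#' Thin orchestration over [writeCohort()]: writes the cohort under
#' `config$inputDir` together with the resolved configuration for
#' provenance.
#'
#' @param config a [pipelineConfig()] with `inputDir` set.
#' @return the manifest data.frame, invisibly.
#' @export
runSimulate <- function(config) {
  if (is.null(config$inputDir)) stop("config$inputDir must be set")
  writeCohort(config$nSubjects, config$inputDir, config$cohort)
}

#' Analyze a cohort on disk
#'
#' End-to-end analysis: for every image listed in the cohort metadata, the
#' interface annotation is loaded, the ROI selected, the profile chain run
#' and summarised; per-subject femoral averages are formed over the
#' available sites; then correlation tables (site level-2/slope against K-L
#' and Noyes; femoral levels and slope against K-L and FAS1) and group
#' comparisons (K-L 0 vs 1, FAS2 1 vs 2) are computed. Every dropped site
#' or skipped comparison is recorded in the run log.
#'
#' Outputs under `config$outDir`: `persite_results.csv` (including the FB
#' rows), `correlation_site.csv`, `correlation_femoral.csv`,
#' `group_comparisons.csv`, `run_log.txt`, `summary.json` and
#' `resolved_config.json`. Re-running on unchanged inputs is bit-identical.
#'
#' @param config a [pipelineConfig()] with `inputDir` and `outDir` set.
#' @return list with elements `results` (per-site + FB data.frame),
#'   `siteTable`, `femoralTable`, `groups`, invisibly.
#' @export
runAnalyze <- function(config) {
  if (is.null(config$inputDir) || is.null(config$outDir))
    stop("config$inputDir and config$outDir must be set")
  inDir <- config$inputDir
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  grades <- readGrades(file.path(inDir, "grades.csv"))
  meta <- utils::read.csv(file.path(inDir, "images_meta.csv"),
                          colClasses = c(subject_id = "character"))
  manifest <- utils::read.csv(file.path(inDir, "manifest.csv"),
                              colClasses = c(subject_id = "character"))

  perSite <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    mm <- meta[meta$subject_id == m$subject_id & meta$site == m$site, ]
    res <- tryCatch({
      img <- readBModePNG(file.path(inDir, m$image_path),
                          imageDepthMm = mm$image_depth_mm,
                          site = m$site, subjectId = m$subject_id)
      ann <- readAnnotation(file.path(inDir, m$annotation_path))
      roi <- selectROI(img, ann, config$roiWidthMm, config$roiHeightMm)
      summarizeROI(roi, m$site, config$referencePitchMm,
                   config$profileSamples, config$slopeSamples)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      note("DROPPED ", m$subject_id, "/", m$site, ": ",
           conditionMessage(res))
    } else {
      perSite[[length(perSite) + 1L]] <- res
      names(perSite)[length(perSite)] <- paste(m$subject_id, m$site,
                                               sep = "/")
    }
  }

  summaryRow <- function(s, subjectId) {
    lv <- levelValues(s)
    data.frame(subject_id = subjectId, site = siteLabel(s),
               level1 = lv[1], level2 = lv[2], level3 = lv[3],
               level4 = lv[4], level5 = lv[5],
               level_all = overallMean(s), slope = intensitySlope(s),
               n_sites_used = s@nSites)
  }

  rows <- list()
  for (sid in unique(grades$subject_id)) {
    mine <- perSite[startsWith(names(perSite), paste0(sid, "/"))]
    if (!length(mine)) {
      note("SUBJECT ", sid, " dropped: no analyzable site")
      next
    }
    for (s in mine) rows[[length(rows) + 1L]] <- summaryRow(s, sid)
    rows[[length(rows) + 1L]] <- summaryRow(femoralAverage(mine), sid)
  }
  results <- do.call(rbind, rows)

  # wide per-subject frame: FB variables + per-site level2/slope + grades
  fb <- results[results$site == "FB", ]
  wide <- merge(grades, fb[, c("subject_id", paste0("level", 1:5),
                               "level_all", "slope")],
                by = "subject_id", all.x = TRUE)
  names(wide)[names(wide) == "slope"] <- "fb_slope"
  for (lv in c(paste0("level", 1:5), "level_all"))
    names(wide)[names(wide) == lv] <- paste0("fb_", lv)
  for (site in SITES) {
    sub <- results[results$site == site, c("subject_id", "level2", "slope")]
    names(sub) <- c("subject_id", paste0(tolower(site), "_level2"),
                    paste0(tolower(site), "_slope"))
    wide <- merge(wide, sub, by = "subject_id", all.x = TRUE)
  }

  sitePairs <- do.call(rbind, lapply(SITES, function(site) {
    v <- c(paste0(tolower(site), "_level2"), paste0(tolower(site), "_slope"))
    g <- c("kl_grade", paste0("noyes_", site))
    expand.grid(variable = v, grading = g, stringsAsFactors = FALSE)
  }))
  siteTable <- correlationTable(wide, sitePairs, config$ciLevel)

  fbPairs <- expand.grid(
    variable = c(paste0("fb_level", 1:5), "fb_level_all", "fb_slope"),
    grading = c("kl_grade", "fas1"), stringsAsFactors = FALSE)
  femoralTable <- correlationTable(wide, fbPairs, config$ciLevel)
  note("NOTE: no multiple-testing correction applied; ",
       "each correlation row is a marginal test")

  fbVars <- c(paste0("fb_level", 1:5), "fb_level_all", "fb_slope")
  groupDefs <- list(list(col = "kl_grade", g = c(0, 1), label = "K-L 0 vs 1"),
                    list(col = "fas2", g = c(1, 2), label = "FAS2 1 vs 2"))
  gRows <- list()
  for (gd in groupDefs) for (v in fbVars) {
    a <- wide[[v]][!is.na(wide[[gd$col]]) & wide[[gd$col]] == gd$g[1]]
    b <- wide[[v]][!is.na(wide[[gd$col]]) & wide[[gd$col]] == gd$g[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      note("SKIPPED t-test ", gd$label, " for ", v,
           ": group sizes ", length(a), " and ", length(b))
      next
    }
    tt <- twoSampleT(a, b, groupLabels = paste0(gd$col, "=", gd$g))
    gRows[[length(gRows) + 1L]] <- data.frame(
      variable = v, comparison = gd$label, n1 = length(a), n2 = length(b),
      mean1 = tt$means[1], mean2 = tt$means[2], t_stat = tt$tStat,
      p = tt$p, stars = significanceStars(tt$p))
  }
  groups <- if (length(gRows)) do.call(rbind, gRows) else NULL

  for (tbl in list(list(results, "persite_results.csv"),
                   list(siteTable, "correlation_site.csv"),
                   list(femoralTable, "correlation_femoral.csv")))
    utils::write.csv(tbl[[1]], file.path(config$outDir, tbl[[2]]),
                     row.names = FALSE)
  if (!is.null(groups))
    utils::write.csv(groups, file.path(config$outDir,
                     "group_comparisons.csv"), row.names = FALSE)
  note("effective n per correlation: ",
       paste(paste0(femoralTable$variable, "/", femoralTable$grading, "=",
                    femoralTable$n), collapse = ", "))
  writeLines(log, file.path(config$outDir, "run_log.txt"))
  jsonlite::write_json(
    list(n_subjects_analyzed = length(unique(results$subject_id)),
         n_site_profiles = sum(results$site != "FB"),
         n_dropped = sum(startsWith(log, "DROPPED"))),
    file.path(config$outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::write_json(cfg, file.path(config$outDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (is.null(results) || !nrow(results))
    stop("no analyzable subjects in ", inDir)
  invisible(list(results = results, siteTable = siteTable,
                 femoralTable = femoralTable, groups = groups))
}

#' Render correlation CSVs as aligned text tables
#'
#' @param dir an output directory written by [runAnalyze()].
#' @return character vector of rendered lines, invisibly (also printed).
#' @export
reportTables <- function(dir) {
  out <- character()
  for (f in c("correlation_site.csv", "correlation_femoral.csv")) {
    path <- file.path(dir, f)
    if (!file.exists(path)) next
    tb <- utils::read.csv(path)
    out <- c(out, paste0("== ", f, " =="),
             sprintf("%-14s %-12s %3s %8s %18s %9s %-4s",
                     "variable", "grading", "n", "r", "95% CI", "p", ""))
    for (i in seq_len(nrow(tb))) {
      ci <- if (is.na(tb$r[i])) "      --        " else
        sprintf("%7.3f to %6.3f", tb$ci_low[i], tb$ci_high[i])
      out <- c(out, sprintf("%-14s %-12s %3d %8s %18s %9s %-4s",
                            tb$variable[i], tb$grading[i], tb$n[i],
                            ifelse(is.na(tb$r[i]), "--",
                                   sprintf("%.3f", tb$r[i])), ci,
                            ifelse(is.na(tb$p[i]), "--",
                                   sprintf("%.4f", tb$p[i])),
                            ifelse(is.na(tb$stars[i]), "",
                                   tb$stars[i])))
    }
    out <- c(out, "")
  }
  cat(out, sep = "\n")
  invisible(out)
}
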