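#' Read a grayscale PNG image with its metadata sidecar record
#'
#' @param path PNG path.
#' @param imageDepthMm imaging depth from the sidecar, mm.
#' @param site,subjectId identity metadata.
#' @return A [BModeImage-class] with 8-bit gray levels (0--255).
#' @export
readBModePNG <- function(path, imageDepthMm, site, subjectId = "") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # grayscale channel
  bModeImage(round(arr * 255), imageDepthMm, site, subjectId)
}

#' Read an interface annotation CSV
#'
#' Expects columns `row`, `col` and `is_center` (exactly one row flagged),
#' the format written by [writeCohort()].
#'
#' @param path CSV path.
#' @return An [InterfaceAnnotation-class].
#' @export
readAnnotation <- function(path) {
  df <- utils::read.csv(path)
  need <- c("row", "col", "is_center")
  if (!all(need %in% names(df)))
    stop("annotation file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  interfaceAnnotation(df[, c("row", "col")],
                      centerCol = df$col[df$is_center == 1][1])
}

#' Read a grade table
#'
#' Expects columns `subject_id`, `kl_grade` and per-site Noyes columns
#' `noyes_MED`, `noyes_SULC`, `noyes_LAT`, which may hold either labels
#' (`"2A"`) or numerics (auto-detected per column). Derives `fas1` and
#' `fas2`.
#'
#' @param path CSV path.
#' @return data.frame with numeric grade columns plus `fas1`, `fas2` (and
#'   `severity` if present in the file).
#' @export
readGrades <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  for (site in SITES) {
    cn <- paste0("noyes_", site)
    if (!cn %in% names(df)) stop("grade table lacks column ", cn)
    if (!is.numeric(df[[cn]])) {
      df[[cn]] <- tryCatch(convertNoyes(df[[cn]]), error = function(e)
        stop("in column ", cn, ": ", conditionMessage(e), call. = FALSE))
    } else if (any(!is.na(df[[cn]]) &
                   (df[[cn]] < 0 | df[[cn]] > 6 | df[[cn]] != round(df[[cn]]))))
      stop("column ", cn, " holds values outside the Noyes range 0..6")
  }
  df$fas1 <- apply(df[, paste0("noyes_", SITES)], 1L, function(z)
    if (anyNA(z)) NA_real_ else sum(z))
  df$fas2 <- fas2Score(df$fas1)
  df
}
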