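#' Convert an arthroscopic Noyes label to its numeric grade
#'
#' The seven-step Noyes cartilage-surface scale is mapped to integers for
#' analysis: 0 -> 0, 1A -> 1, 1B -> 2, 2A -> 3, 2B -> 4, 3A -> 5, 3B -> 6.
#'
#' @param label character vector of Noyes labels.
#' @return integer vector of grades 0--6 (NA input stays NA).
#' @examples
#' convertNoyes(c("0", "2A", "3B"))
#' @export
convertNoyes <- function(label) {
  map <- c("0" = 0L, "1A" = 1L, "1B" = 2L, "2A" = 3L,
           "2B" = 4L, "3A" = 5L, "3B" = 6L)
  label <- toupper(trimws(as.character(label)))
  out <- map[label]
  bad <- !is.na(label) & is.na(out)
  if (any(bad))
    stop("unknown Noyes label(s): ", paste(unique(label[bad]), collapse = ", "))
  unname(out)
}

#' Composite femoral arthroscopic score FAS1
#'
#' Sum of the three site-specific numeric Noyes grades (MED, SULC, LAT),
#' ranging 0--18. Missing if any site grade is missing.
#'
#' @param noyes numeric(3) of site grades in 0..6 (any order; names ignored).
#' @return integer in 0..18, or NA.
#' @examples
#' fas1Score(c(6, 6, 6))  # 18
#' @export
fas1Score <- function(noyes) {
  if (length(noyes) != 3L)
    stop("fas1Score expects exactly three site grades")
  if (anyNA(noyes)) return(NA_real_)
  if (any(noyes < 0 | noyes > 6 | noyes != round(noyes)))
    stop("Noyes numeric grades must be integers in 0..6")
  sum(noyes)
}

#' Binned femoral arthroscopic score FAS2
#'
#' FAS1 is discretized into four grades for group comparisons:
#' 0 -> 0; 1--6 -> 1; 7--12 -> 2; 13--18 -> 3.
#'
#' @param fas1Value integer FAS1 value in 0..18 (vectorized; NA stays NA).
#' @return integer grade 0--3.
#' @examples
#' fas2Score(c(0, 6, 7, 18))  # 0 1 2 3
#' @export
fas2Score <- function(fas1Value) {
  out <- rep(NA_real_, length(fas1Value))
  ok <- !is.na(fas1Value)
  if (any(fas1Value[ok] < 0 | fas1Value[ok] > 18))
    stop("FAS1 values must lie in 0..18")
  out[ok] <- findInterval(fas1Value[ok], c(1, 7, 13))
  out
}
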