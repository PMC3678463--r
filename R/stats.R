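#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rank correlation on midranks (pairwise-complete
#' observations only) with a two-sided p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom — the
#' default behaviour of mainstream statistics packages for tied ordinal
#' data. For small samples an exact permutation p-value is available.
#'
#' @param x,y numeric/ordinal vectors of equal length.
#' @param pMethod `"t"` (default) or `"exact"` (full permutation null of the
#'   rank correlation; n must be at most 8).
#' @return list with `r`, `n` (pairwise-complete count) and `p`.
#' @examples
#' spearmanCorrelation(1:10, (1:10)^2)$r  # 1: invariant to monotone maps
#' @export
spearmanCorrelation <- function(x, y, pMethod = c("t", "exact")) {
  pMethod <- match.arg(pMethod)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 pairwise-complete observations (got ", n, ")")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y after removing missing pairs")
  r <- stats::cor(x, y, method = "spearman")
  if (pMethod == "exact") {
    if (n > 8L)
      stop("exact permutation p-value supported only for n <= 8")
    rx <- rank(x); ry <- rank(y)
    perms <- permuteAll(n)
    rs <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(r = r, n = n, p = p)
}

# all permutations of 1..n as a matrix (n! rows); recursion, n <= 8
permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  k <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[k + seq_len(nrow(sub)), ] <- block
    k <- k + nrow(sub)
  }
  out
}

#' Fisher r-to-Z confidence interval for a correlation coefficient
#'
#' Transforms r to `z = atanh(r)`, whose sampling distribution is
#' approximately normal with standard deviation `1/sqrt(n - 3)`, builds the
#' symmetric interval on the z scale and back-transforms with `tanh`
#' (Altman-Gardner construction).
#'
#' @param r correlation coefficient, |r| < 1.
#' @param n sample size, at least 4.
#' @param level confidence level (default 0.95).
#' @return numeric(2): lower and upper bounds.
#' @examples
#' round(fisherCI(0.600, 31), 3)  # 0.312 0.787
#' @export
fisherCI <- function(r, n, level = 0.95) {
  if (n < 4) stop("n must be at least 4")
  if (abs(r) >= 1)
    stop("|r| = 1 gives a degenerate interval; fisherCI requires |r| < 1")
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(tanh(z - half), tanh(z + half))
}

#' Two-sample t comparison
#'
#' Classical pooled-variance (Student's) two-sample t-test by default, with
#' the Welch variant behind a flag. Thin wrapper over [stats::t.test()]
#' returning the fields needed for group-comparison tables.
#'
#' @param a,b numeric vectors (each at least 2 non-missing values).
#' @param equalVariance pooled variance if `TRUE` (default), Welch otherwise.
#' @param groupLabels length-2 character labels for reporting.
#' @return list with `groupLabels`, `means`, `tStat`, `df`, `p`.
#' @export
twoSampleT <- function(a, b, equalVariance = TRUE,
                       groupLabels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (equalVariance && stats::var(c(a - mean(a), b - mean(b))) == 0)
    stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = equalVariance)
  list(groupLabels = groupLabels, means = c(mean(a), mean(b)),
       tStat = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Significance stars
#'
#' @param p numeric vector of p-values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `""` (NA for NA input).
#' @export
significanceStars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
  out
}

#' Correlation table for variable/grading pairs
#'
#' For each requested pair of a quantitative ultrasound variable and an
#' ordinal grading column, computes the Spearman correlation on
#' pairwise-complete subjects, the Fisher r-to-Z confidence interval, the
#' p-value and significance stars. Pairs with fewer than 4 complete
#' observations (or zero variance) are returned as NA rows rather than
#' failing, so a table over a partially missing cohort always renders.
#'
#' No multiple-testing correction is applied; each row is a marginal test.
#'
#' @param data data.frame with one row per subject.
#' @param pairs data.frame with character columns `variable` and `grading`
#'   naming columns of `data`.
#' @param ciLevel confidence level for the Fisher interval.
#' @return data.frame: `variable`, `grading`, `n`, `r`, `ci_low`, `ci_high`,
#'   `p`, `stars`.
#' @export
correlationTable <- function(data, pairs, ciLevel = 0.95) {
  if (!nrow(pairs)) stop("pairs must contain at least one row")
  missingCols <- setdiff(unique(c(pairs$variable, pairs$grading)),
                         names(data))
  if (length(missingCols))
    stop("columns not in data: ", paste(missingCols, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    v <- pairs$variable[i]; g <- pairs$grading[i]
    res <- tryCatch(spearmanCorrelation(data[[v]], data[[g]]),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(variable = v, grading = g, n = sum(!is.na(data[[v]]) &
                 !is.na(data[[g]])), r = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, stars = NA_character_)
    } else {
      ci <- if (abs(res$r) < 1) fisherCI(res$r, res$n, ciLevel)
            else c(res$r, res$r)
      data.frame(variable = v, grading = g, n = res$n, r = res$r,
                 ci_low = ci[1], ci_high = ci[2], p = res$p,
                 stars = significanceStars(res$p))
    }
  })
  do.call(rbind, rows)
}
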