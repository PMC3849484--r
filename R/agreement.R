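#' Assemble a paired-counts table
#'
#' @param imageId character vector of unique image identifiers.
#' @param countA,countB non-negative counts from the two methods compared.
#' @param stratum optional grouping label per image (e.g. background
#'   presence or LOW/HIGH complexity).
#' @return data.frame with columns `imageId`, `countA`, `countB` and
#'   optionally `stratum`.
#' @export
pairedCounts <- function(imageId, countA, countB, stratum = NULL) {
  imageId <- as.character(imageId)
  if (anyDuplicated(imageId)) stop("image ids must be unique", call. = FALSE)
  if (length(countA) != length(imageId) || length(countB) != length(imageId))
    stop("countA and countB must match imageId in length", call. = FALSE)
  if (any(countA < 0) || any(countB < 0))
    stop("counts must be >= 0", call. = FALSE)
  out <- data.frame(imageId = imageId, countA = as.numeric(countA),
                    countB = as.numeric(countB), stringsAsFactors = FALSE)
  if (!is.null(stratum)) {
    if (length(stratum) == 1L) stratum <- rep(stratum, length(imageId))
    if (length(stratum) != length(imageId))
      stop("stratum must match imageId in length", call. = FALSE)
    out$stratum <- as.character(stratum)
  }
  out
}

.checkPairs <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("countA", "countB") %in% names(pairs)))
    stop("pairs must be a data.frame with countA and countB columns",
         call. = FALSE)
  invisible(TRUE)
}

#' Bland-Altman agreement analysis of paired counts
#'
#' Differences are `countA - countB`; the summary reports their mean, the
#' sample standard deviation (n - 1 denominator) and the limits of
#' agreement `mean +/- multiplier * SD`, plus the per-image points
#' (mean of the pair, difference) for plotting.
#'
#' @param pairs data.frame from [pairedCounts()] (columns `countA`,
#'   `countB`, optionally `imageId`).
#' @param multiplier limits-of-agreement multiplier, default 1.96.
#' @return an [AgreementSummary-class].
#' @examples
#' p <- pairedCounts(1:3, c(10, 20, 30), c(12, 18, 33))
#' blandAltman(p)  # mean diff -1, SD sqrt(7)
#' @export
blandAltman <- function(pairs, multiplier = 1.96) {
  .checkPairs(pairs)
  n <- nrow(pairs)
  if (n < 2)
    stop("Bland-Altman analysis needs at least 2 pairs (SD undefined)",
         call. = FALSE)
  diffs <- pairs$countA - pairs$countB
  m <- mean(diffs)
  s <- sd(diffs)
  ids <- if ("imageId" %in% names(pairs)) as.character(pairs$imageId)
         else as.character(seq_len(n))
  new("AgreementSummary", n = as.integer(n), meanDiff = m, sdDiff = s,
      loaLow = m - multiplier * s, loaHigh = m + multiplier * s,
      multiplier = multiplier,
      points = data.frame(imageId = ids,
                          pairMean = (pairs$countA + pairs$countB) / 2,
                          diff = diffs, stringsAsFactors = FALSE))
}

#' Survival curve of absolute paired count differences
#'
#' The empirical survival function of `|countA - countB|`:
#' `P(|diff| >= d) = #(|diff_i| >= d) / n`, tabulated at `d = 0` and every
#' distinct observed absolute difference. This is the cumulative
#' probability-of-difference curve used to compare quantification methods;
#' absolute differences are used because the question is the magnitude of
#' disagreement.
#'
#' @param pairs data.frame from [pairedCounts()].
#' @return a [DifferenceCurve-class]; use [probabilityAtLeast()] to
#'   evaluate it at arbitrary thresholds.
#' @examples
#' p <- pairedCounts(1:4, c(10, 20, 80, 100), c(10, 30, 30, 40))
#' probabilityAtLeast(differenceCurve(p), 50)  # 0.5
#' @export
differenceCurve <- function(pairs) {
  .checkPairs(pairs)
  if (nrow(pairs) == 0) stop("no pairs supplied", call. = FALSE)
  ad <- abs(pairs$countA - pairs$countB)
  d <- sort(unique(c(0, ad)))
  prob <- vapply(d, function(t) mean(ad >= t), numeric(1))
  new("DifferenceCurve", curve = data.frame(d = d, prob = prob),
      absDiffs = as.numeric(ad))
}

#' Stratified agreement comparison
#'
#' Splits the pairs by a grouping column and computes, per stratum, the
#' Bland-Altman summary and the difference curve. Strata with fewer than 2
#' pairs get the curve only; their Bland-Altman slot is `NULL` and they are
#' flagged.
#'
#' @param pairs data.frame from [pairedCounts()] carrying the grouping
#'   column.
#' @param by name of the grouping column, default `"stratum"`.
#' @param multiplier limits-of-agreement multiplier, default 1.96.
#' @return named list (one element per stratum), each a list with elements
#'   `n`, `blandAltman` ([AgreementSummary-class] or `NULL`), `curve`
#'   ([DifferenceCurve-class]) and `flagged` (TRUE when n < 2).
#' @export
stratifiedCompare <- function(pairs, by = "stratum", multiplier = 1.96) {
  .checkPairs(pairs)
  if (!by %in% names(pairs))
    stop("unknown grouping column: '", by, "'", call. = FALSE)
  groups <- split(pairs, pairs[[by]])
  lapply(groups, function(g) {
    small <- nrow(g) < 2
    list(n = nrow(g),
         blandAltman = if (small) NULL else blandAltman(g, multiplier),
         curve = differenceCurve(g),
         flagged = small)
  })
}
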