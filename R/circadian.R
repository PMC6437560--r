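# Circadian similarity: a NaN-tolerant two-way consistency intra-class
# correlation over day x epoch feature matrices. Epochs are the rated
# targets and days the raters, so the statistic measures how reproducible a
# subject's day/evening/night profile is from day to day, ignoring overall
# day-level shifts.

#' NaN-tolerant two-way consistency ICC
#'
#' Computes the single-measure, two-way consistency intra-class correlation
#' (the ICC(3,1) form) of a day x epoch matrix, with epochs as targets and
#' days as raters. All means and sums are taken over observed cells only and
#' degrees of freedom are reduced accordingly, so the statistic degrades
#' gracefully with missing entries and reproduces the complete-data ANOVA
#' ICC exactly when nothing is missing.
#'
#' Returns `NA` (the undefined marker, not an error) when the between-epoch
#' mean square is not estimable or both mean squares are zero (e.g. a
#' constant matrix).
#'
#' @param mat Numeric matrix with days in rows and exactly 3 epoch columns;
#'   `NA` entries allowed.
#' @param transpose Set `TRUE` to rate days as targets instead (sensitivity
#'   analysis); the default orientation is epochs-as-targets.
#' @return A single numeric ICC in \[-1, 1\], or `NA` when undefined.
#'   Attributes `msTarget`, `msError`, `dfError`, `nRaters` and
#'   `orientation` record the ANOVA components used.
#' @export
nanICC <- function(mat, transpose = FALSE) {
  mat <- as.matrix(mat)
  if (!transpose && ncol(mat) != 3) {
    stop("insufficient data: matrix must have exactly 3 epoch columns")
  }
  if (transpose) mat <- t(mat)
  obsPerRow <- rowSums(!is.na(mat))
  if (nrow(mat) < 2 || sum(obsPerRow >= 2) < 2) {
    stop("insufficient data: need at least 2 days with at least 2 observed epochs")
  }
  obs <- !is.na(mat)
  x <- mat[obs]
  nObs <- length(x)
  grand <- mean(x)
  colN <- colSums(obs); rowN <- rowSums(obs)
  colM <- colMeans(mat, na.rm = TRUE)
  rowM <- rowMeans(mat, na.rm = TRUE)
  usedCols <- colN > 0; usedRows <- rowN > 0
  ssCol <- sum(colN[usedCols] * (colM[usedCols] - grand)^2)
  ssRow <- sum(rowN[usedRows] * (rowM[usedRows] - grand)^2)
  ssTot <- sum((x - grand)^2)
  ssErr <- ssTot - ssCol - ssRow
  dfCol <- sum(usedCols) - 1L
  dfRow <- sum(usedRows) - 1L
  dfErr <- (nObs - 1L) - dfCol - dfRow
  out <- NA_real_
  msCol <- msErr <- NA_real_
  if (dfCol >= 1 && dfErr >= 1) {
    msCol <- ssCol / dfCol
    msErr <- ssErr / dfErr
    k <- sum(usedRows)                       # raters = days with data
    den <- msCol + (k - 1) * msErr
    if (is.finite(den) && den > 0) out <- (msCol - msErr) / den
  }
  attr(out, "msTarget") <- msCol
  attr(out, "msError") <- msErr
  attr(out, "dfError") <- dfErr
  attr(out, "nRaters") <- sum(usedRows)
  attr(out, "orientation") <- if (transpose) "days_as_targets" else "epochs_as_targets"
  out
}

#' Per-subject circadian similarity score
#'
#' Builds the day x epoch matrix of a feature from a subject's daily epoch
#' table (valid days only), applies [nanICC()] and enforces the
#' minimum-days inclusion rule. Exclusion is a value, not an error.
#'
#' @param epochTable Output of [buildDailyEpochTable()] (or any data frame
#'   with columns `day`, `epoch`, `day_valid` and the feature column).
#' @param feature Column to score: `"still_minutes"`, `"unique_locations"`
#'   or `"unlock_minutes"`.
#' @param minDays Minimum number of valid days (default 20).
#' @param transpose Passed to [nanICC()].
#' @return List with `included`, `icc` (`NA` when excluded or undefined),
#'   `nDaysUsed` and `orientation`.
#' @export
circadianSimilarity <- function(epochTable,
                                feature = c("still_minutes",
                                            "unique_locations",
                                            "unlock_minutes"),
                                minDays = 20, transpose = FALSE) {
  feature <- match.arg(feature)
  tab <- epochTable[epochTable$day_valid & !is.na(epochTable[[feature]]), ,
                    drop = FALSE]
  days <- sort(unique(tab$day))
  if (length(days) < minDays) {
    return(list(included = FALSE, icc = NA_real_,
                nDaysUsed = length(days),
                orientation = if (transpose) "days_as_targets" else "epochs_as_targets"))
  }
  epochs <- c("day", "evening", "night")
  m <- matrix(NA_real_, length(days), 3, dimnames = list(NULL, epochs))
  m[cbind(match(tab$day, days), match(tab$epoch, epochs))] <- tab[[feature]]
  icc <- nanICC(m, transpose = transpose)
  list(included = TRUE, icc = as.numeric(icc), nDaysUsed = length(days),
       orientation = attr(icc, "orientation"))
}
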