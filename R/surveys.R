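# PHQ survey scoring: item validation, instrument totals, severity
# categories and averaging of repeated ecological momentary assessments.

.phqItems <- c(PHQ8 = 8L, PHQ4 = 4L)

#' Score a PHQ instrument response
#'
#' Sum of the ordinal 0-3 item scores. The PHQ-8 total lies in 0-24 and the
#' PHQ-4 total in 0-12; the PHQ-2 depression score of a PHQ-4 response is
#' the sum of its first two (depression) items, see [phq2Score()].
#'
#' @param itemScores Integer vector of item scores, each in 0-3.
#' @param instrument `"PHQ8"` or `"PHQ4"`.
#' @return Integer total.
#' @export
scorePHQ <- function(itemScores, instrument = c("PHQ8", "PHQ4")) {
  instrument <- match.arg(instrument)
  n <- .phqItems[[instrument]]
  if (length(itemScores) != n) {
    stop("validation error: ", instrument, " requires ", n, " item scores")
  }
  if (anyNA(itemScores)) {
    stop("validation error: missing item scores are not accepted (no prorating)")
  }
  if (any(itemScores < 0 | itemScores > 3 | itemScores != round(itemScores))) {
    stop("validation error: item scores must be integers in 0-3")
  }
  as.integer(sum(itemScores))
}

#' PHQ-2 depression score from a PHQ-4 response
#'
#' Items 1-2 of the PHQ-4 are its depression items (the PHQ-2); items 3-4
#' are the anxiety items.
#'
#' @param phq4Items Integer vector of 4 item scores.
#' @return Integer PHQ-2 total in 0-6.
#' @export
phq2Score <- function(phq4Items) {
  scorePHQ(phq4Items, "PHQ4")                 # validates
  as.integer(sum(phq4Items[1:2]))
}

#' PHQ-8 severity cutpoints
#'
#' The conventional severity bands: 0-4 minimal, 5-9 mild, 10-14 moderate,
#' 15-19 moderately severe, 20-24 severe. Kept as a configuration table so
#' alternative banding schemes can be supplied.
#'
#' @return `data.frame` with columns `lower`, `upper`, `label`.
#' @export
phqSeverityCutpoints <- function() {
  data.frame(lower = c(0, 5, 10, 15, 20),
             upper = c(4, 9, 14, 19, 24),
             label = c("minimal", "mild", "moderate",
                       "moderately_severe", "severe"),
             stringsAsFactors = FALSE)
}

#' Severity category of a PHQ-8 total
#'
#' @param phq8Total Integer total in 0-24 (vectorized).
#' @param cutpoints Banding table, default [phqSeverityCutpoints()].
#' @return Factor with the cutpoint labels as levels.
#' @export
severityCategory <- function(phq8Total, cutpoints = phqSeverityCutpoints()) {
  if (any(is.na(phq8Total)) ||
      any(phq8Total < 0 | phq8Total > 24 | phq8Total != round(phq8Total))) {
    stop("validation error: PHQ-8 totals must be integers in 0-24")
  }
  idx <- findInterval(phq8Total, cutpoints$lower)
  factor(cutpoints$label[idx], levels = cutpoints$label)
}

#' Average repeated EMA administrations
#'
#' Arithmetic mean of instrument totals across administrations. One
#' administration is sufficient for inclusion; zero administrations yield
#' the exclusion marker.
#'
#' @param totals Numeric vector of per-administration totals.
#' @return List with `included`, `meanScore` (`NA` when excluded) and
#'   `nAdministrations`.
#' @export
emaAverage <- function(totals) {
  totals <- totals[!is.na(totals)]
  if (!length(totals)) {
    list(included = FALSE, meanScore = NA_real_, nAdministrations = 0L)
  } else {
    list(included = TRUE, meanScore = mean(totals),
         nAdministrations = length(totals))
  }
}

#' Per-subject score table from a long survey response table
#'
#' Scores every administration, averages repeated EMAs per instrument and
#' attaches the PHQ-8 severity category.
#'
#' @param surveys Long `data.frame` with columns `subject_id`, `instrument`,
#'   `item_index`, `score`, `timestamp` (one row per item).
#' @return `data.frame` with one row per subject: `subject_id`, `phq8`,
#'   `phq4_mean`, `phq2_mean`, `n_phq4`, `severity`.
#' @export
scoreSurveyTable <- function(surveys) {
  out <- lapply(split(surveys, surveys$subject_id), function(ss) {
    adminTotals <- function(instr, scorer) {
      sel <- ss[ss$instrument == instr, , drop = FALSE]
      if (!nrow(sel)) return(numeric(0))
      vapply(split(sel, as.numeric(sel$timestamp)), function(a) {
        as.numeric(scorer(a$score[order(a$item_index)]))
      }, numeric(1))
    }
    phq8s <- adminTotals("PHQ8", function(x) scorePHQ(x, "PHQ8"))
    phq4s <- adminTotals("PHQ4", function(x) scorePHQ(x, "PHQ4"))
    phq2s <- adminTotals("PHQ4", phq2Score)
    phq8 <- emaAverage(phq8s)
    phq4 <- emaAverage(phq4s)
    phq2 <- emaAverage(phq2s)
    data.frame(
      subject_id = ss$subject_id[1],
      phq8 = phq8$meanScore,
      phq4_mean = phq4$meanScore,
      phq2_mean = phq2$meanScore,
      n_phq4 = phq4$nAdministrations,
      severity = if (phq8$included && length(phq8s) == 1)
        as.character(severityCategory(phq8s[1])) else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
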