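## Descriptive evaluation statistics: failure rates, Likert summaries,
## SUS scoring/banding, additional-veins summaries.

#' Failure-rate table by BMI class
#'
#' Tallies venipuncture attempts per BMI class (an opaque categorical
#' label; no numeric BMI boundaries are assumed) and appends a pooled
#' Total row. The failure rate is `100 * failures / attempts`, half-up
#' rounded to one decimal.
#'
#' @param records data.frame with at least columns `bmi_class` (character
#'   or factor) and `hit` (logical); one row per marked attempt.
#' @return data.frame with columns `class`, `failures`, `attempts`,
#'   `rate` (percent, 1 decimal), classes in sorted label order and a
#'   final "Total" row.
#' @examples
#' rec <- data.frame(bmi_class = rep(c("1", "2"), c(4, 6)),
#'                   hit = c(TRUE, TRUE, FALSE, TRUE, rep(TRUE, 5), FALSE))
#' failureRateTable(rec)
#' @export
failureRateTable <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    .fail("records must be a nonempty data.frame")
  if (!all(c("bmi_class", "hit") %in% names(records)))
    .fail("records needs columns 'bmi_class' and 'hit'")
  if (any(is.na(records$hit))) .fail("every record must carry a hit value")
  cls <- sort(unique(as.character(records$bmi_class)))
  rows <- lapply(cls, function(cl) {
    sub <- records[records$bmi_class == cl, ]
    f <- sum(!sub$hit); a <- nrow(sub)
    data.frame(class = cl, failures = f, attempts = a,
               rate = .roundHalfUp(100 * f / a, 1))
  })
  f <- sum(!records$hit); a <- nrow(records)
  rows <- c(rows, list(data.frame(class = "Total", failures = f, attempts = a,
                                  rate = .roundHalfUp(100 * f / a, 1))))
  do.call(rbind, rows)
}

#' Expand per-class attempt counts into records
#'
#' Convenience for feeding printed (failures / attempts) tallies through
#' [failureRateTable()].
#'
#' @param counts data.frame with columns `bmi_class`, `failures`,
#'   `attempts`.
#' @return data.frame of attempt records (`bmi_class`, `hit`).
#' @examples
#' cnt <- data.frame(bmi_class = c("1", "2"), failures = c(2, 3),
#'                   attempts = c(10, 12))
#' failureRateTable(attemptsFromCounts(cnt))
#' @export
attemptsFromCounts <- function(counts) {
  stopifnot(all(c("bmi_class", "failures", "attempts") %in% names(counts)))
  if (any(counts$failures > counts$attempts))
    .fail("failures cannot exceed attempts")
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(bmi_class = as.character(counts$bmi_class[i]),
               hit = rep(c(FALSE, TRUE),
                         c(counts$failures[i],
                           counts$attempts[i] - counts$failures[i])))
  }))
}

#' Per-item Likert summary
#'
#' Mean (2 decimals), sample standard deviation (n - 1 denominator, 3
#' decimals) and mode (ties broken toward the larger score) for each item
#' column of a 1-5 Likert response table. Half-up rounding throughout.
#'
#' @param table data.frame of integer scores in 1..5; one row per
#'   respondent, one column per item (a leading `id` column is ignored).
#' @return data.frame with columns `item`, `mean`, `sd`, `mode`.
#' @examples
#' resp <- data.frame(A = c(5, 4, 5), B = c(3, 3, 4))
#' likertSummary(resp)
#' @export
likertSummary <- function(table) {
  stopifnot(is.data.frame(table))
  items <- setdiff(names(table), "id")
  if (nrow(table) < 2) .fail("need >= 2 respondents for a sample SD")
  for (it in items) {
    v <- table[[it]]
    if (any(is.na(v)) || any(v != as.integer(v)) || any(v < 1) || any(v > 5))
      .fail("item %s has scores outside 1..5", it)
  }
  do.call(rbind, lapply(items, function(it) {
    v <- as.integer(table[[it]])
    tab <- table(v)
    modes <- as.integer(names(tab)[tab == max(tab)])
    data.frame(item = it,
               mean = .roundHalfUp(mean(v), 2),
               sd = .roundHalfUp(stats::sd(v), 3),
               mode = max(modes))
  }))
}

#' System Usability Scale score
#'
#' Standard SUS scoring of one 10-item response: odd items contribute
#' `score - 1`, even items `5 - score`, and the sum is scaled by 2.5 onto
#' 0-100. Items alternate positively and negatively worded, per the
#' standard instrument.
#'
#' @param response numeric vector of exactly 10 integer scores in 1..5.
#' @return Score in \[0, 100\].
#' @examples
#' susScore(rep(3, 10))                 # 50
#' susScore(rep(c(5, 1), 5))            # 100
#' @export
susScore <- function(response) {
  if (length(response) != 10)
    .fail("a SUS response has exactly 10 items (got %d)", length(response))
  if (any(is.na(response)) || any(response != as.integer(response)) ||
      any(response < 1) || any(response > 5))
    .fail("SUS scores must be integers in 1..5")
  odd <- response[c(1, 3, 5, 7, 9)]
  even <- response[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' SUS acceptability band
#'
#' Bangor-style interpretation bands: above 70 is acceptable, below 50 a
#' cause of significant concern, and 50-70 (inclusive) marginally
#' acceptable.
#'
#' @param score SUS score in \[0, 100\].
#' @return One of "acceptable", "marginal", "concern".
#' @examples
#' susBand(76.75)
#' susBand(70)
#' @export
susBand <- function(score) {
  if (length(score) != 1 || !is.finite(score) || score < 0 || score > 100)
    .fail("SUS score must be a single number in [0, 100]")
  if (score > 70) "acceptable" else if (score < 50) "concern" else "marginal"
}

#' Additional-veins summary
#'
#' Mean and sample SD (1 decimal, half-up) of per-patient counts of veins
#' found with the device beyond those visible by traditional inspection,
#' optionally restricted to a subgroup.
#'
#' @param counts non-negative integer vector, one element per patient.
#' @param subset optional logical vector selecting a subgroup.
#' @return Named list with `mean`, `sd` and `n`.
#' @examples
#' additionalVeinsSummary(c(1, 2, 3))
#' @export
additionalVeinsSummary <- function(counts, subset = NULL) {
  if (!is.null(subset)) {
    stopifnot(length(subset) == length(counts))
    counts <- counts[subset]
  }
  if (length(counts) < 2) .fail("need >= 2 counts for a sample SD")
  if (any(counts < 0)) .fail("counts must be non-negative")
  list(mean = .roundHalfUp(mean(counts), 1),
       sd = .roundHalfUp(stats::sd(counts), 1),
       n = length(counts))
}
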