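# Small report-arithmetic helpers used by the cohort and timing summaries.

#' Parse an H:MM:SS duration into seconds
#'
#' Accepts `H:MM:SS` or `HH:MM:SS` (and bare `MM:SS`).
#'
#' @param x character vector of durations
#' @return numeric seconds
#' @examples
#' parseHmsDuration("1:27:41")  # 5261
#' @export
parseHmsDuration <- function(x) {
  vapply(x, function(s) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(s), ":", fixed = TRUE)[[1]]))
    if (anyNA(parts) || length(parts) < 2L || length(parts) > 3L)
      stop("cannot parse duration: '", s, "'")
    if (length(parts) == 2L) parts <- c(0, parts)
    parts[1] * 3600 + parts[2] * 60 + parts[3]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Percent reduction from a baseline
#'
#' `100 * (before - after) / before`, e.g. for interpretation-time savings.
#'
#' @param before,after numeric values on the same scale
#' @return percentage reduction
#' @examples
#' percentReduction(parseHmsDuration("1:27:41"), parseHmsDuration("0:20:03"))
#' @export
percentReduction <- function(before, after) {
  if (any(before <= 0)) stop("baseline must be positive")
  100 * (before - after) / before
}

#' Format a count with its percentage of a total
#'
#' Cohort-table convention: `"count (percent)"` with the percentage rounded to
#' one decimal place, e.g. `formatCountPercent(140, 178)` is `"140 (78.7)"`.
#'
#' @param count,total non-negative counts
#' @param digits decimal places for the percentage
#' @return character
#' @export
formatCountPercent <- function(count, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  sprintf(paste0("%d (%.", digits, "f)"), as.integer(count),
          round(100 * count / total, digits))
}
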