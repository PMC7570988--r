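#' Sadeh regression constants
#'
#' The per-minute probability-of-sleep score is
#' `PS = 7.601 - 0.065 * AVG - 1.08 * NAT - 0.056 * SD - 0.703 * LG`
#' where, for the minute being scored: AVG is the mean activity count
#' over an 11-minute window centred on it, NAT the number of minutes
#' in that window with counts in \[50, 100), SD the standard deviation
#' of the counts of the 5 preceding minutes, and LG the natural log of
#' the current minute's count plus one.  A minute is scored asleep
#' when PS >= 0.  The constants live here, in one auditable block, so
#' an alternative calibration can be swapped in.
#'
#' @return Named numeric vector of the regression constants.
#' @export
sadeh_constants <- function() {
  c(intercept = 7.601, avg = -0.065, nat = -1.08, sd = -0.056, lg = -0.703)
}

#' Sadeh sleep/wake scoring of actigraphy counts
#'
#' Scores each minute of a per-minute activity-count series as asleep
#' or awake with the Sadeh regression (see [sadeh_constants()] for the
#' formula).  Windows are clamped at the record edges: statistics are
#' taken over the minutes actually available (the SD term is 0 when
#' fewer than two preceding minutes exist).
#'
#' @param counts Non-negative numeric vector of per-minute activity
#'   counts, length >= 11.
#' @param constants Regression constants, default [sadeh_constants()].
#' @param nat_range Count band for the NAT term, default \[50, 100).
#' @return A tibble with `minute` (0-based), `score` (PS value) and
#'   `asleep` (logical).
#' @export
#' @examples
#' sadeh_scores(rep(0, 20))$asleep       # quiescence scores as sleep
#' sadeh_scores(rep(1000, 20))$asleep    # sustained movement as wake
sadeh_scores <- function(counts, constants = sadeh_constants(),
                         nat_range = c(50, 100)) {
  if (length(counts) < 11L) {
    stop("at least 11 minutes of counts are required", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be non-negative and free of NA", call. = FALSE)
  }
  n <- length(counts)
  is_nat <- counts >= nat_range[1] & counts < nat_range[2]
  # prefix sums for O(1) clamped-window statistics
  cs <- c(0, cumsum(counts))
  cs_nat <- c(0, cumsum(is_nat))
  lo <- pmax(seq_len(n) - 5L, 1L)
  hi <- pmin(seq_len(n) + 5L, n)
  win_n <- hi - lo + 1L
  avg <- (cs[hi + 1L] - cs[lo]) / win_n
  nat <- cs_nat[hi + 1L] - cs_nat[lo]
  sd5 <- vapply(seq_len(n), function(i) {
    prev <- counts[seq.int(max(1L, i - 5L), length.out = min(5L, i - 1L))]
    if (length(prev) < 2L) 0 else stats::sd(prev)
  }, numeric(1))
  lg <- log(counts + 1)
  ps <- constants[["intercept"]] + constants[["avg"]] * avg +
    constants[["nat"]] * nat + constants[["sd"]] * sd5 +
    constants[["lg"]] * lg
  tibble::tibble(minute = seq_len(n) - 1L, score = ps, asleep = ps >= 0)
}
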