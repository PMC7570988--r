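#' REM-to-non-REM ratio (RNR)
#'
#' Percentage ratio of REM minutes to non-REM *sleep* minutes
#' (Light + Deep); higher values are conventionally associated with
#' better sleep quality.  By default Wake is excluded from the
#' denominator ("non-REM" is read as non-REM sleep); set
#' `include_wake = TRUE` for the alternative reading in which every
#' non-REM epoch, Wake included, counts.
#'
#' @param hyp A [hypnogram()].
#' @param include_wake Include Wake minutes in the denominator
#'   (default FALSE).
#' @return RNR in percent.
#' @export
#' @examples
#' h <- hypnogram(rep(c("REM", "Light"), c(30, 120)))
#' rnr(h)  # 25: 15 REM minutes over 60 non-REM sleep minutes
rnr <- function(hyp, include_wake = FALSE) {
  mins <- stage_minutes(hyp)
  denom <- mins[["Light"]] + mins[["Deep"]] +
    if (include_wake) mins[["Wake"]] else 0
  if (denom <= 0) {
    stop("RNR is undefined: no non-REM sleep in the hypnogram",
         call. = FALSE)
  }
  100 * mins[["REM"]] / denom
}

#' Stage-shift index (SSI)
#'
#' Number of sleep-stage shifts divided by the total sleep time in
#' hours; lower values indicate more consolidated sleep.  By default
#' every change of label between adjacent epochs is counted, including
#' shifts into and out of Wake, over the whole record; with
#' `count_wake_shifts = FALSE` Wake epochs are removed first and only
#' shifts between sleep stages are counted.  TST is always the
#' non-Wake time.
#'
#' @param hyp A [hypnogram()].
#' @param count_wake_shifts Count transitions involving Wake
#'   (default TRUE).
#' @return Shifts per hour of total sleep time.
#' @export
#' @examples
#' h <- hypnogram(c("Light", "Light", "Deep", "Deep",
#'                  "REM", "REM", "Light", "Light"))
#' ssi(h)  # 3 shifts over 4 minutes of sleep = 45 per hour
ssi <- function(hyp, count_wake_shifts = TRUE) {
  es <- epoch_seconds(hyp)
  stages <- as.character(hyp)
  tst_hours <- sum(stages != "Wake", na.rm = TRUE) * es / 3600
  if (tst_hours <= 0) {
    stop("SSI is undefined: total sleep time is zero", call. = FALSE)
  }
  seq_ <- if (count_wake_shifts) stages else stages[stages != "Wake"]
  n_shift <- sum(seq_[-1] != seq_[-length(seq_)], na.rm = TRUE)
  n_shift / tst_hours
}

#' Sleep/wake summary indices from a binary state sequence
#'
#' Computes the four classical indices from any per-step sleep/wake
#' sequence -- EEG-derived (30-s epochs, Wake vs any sleep stage) or
#' actigraphy-derived (1-min steps):
#' sleep efficiency SE = sleep steps / total steps, total sleep time
#' TST = sleep minutes, sleep-onset latency SOL = minutes from record
#' start to the first sleep step, and wake after sleep onset WASO =
#' wake minutes after that first sleep step.  Sleep onset is the first
#' sleep-scored step (no consecutive-epoch smoothing).
#'
#' @param asleep Logical (or 0/1) vector, `TRUE` = asleep.
#' @param step_minutes Duration of one step in minutes (0.5 for 30-s
#'   EEG epochs, 1 for actigraphy).
#' @return A one-row tibble with `se` (fraction in \[0, 1\]),
#'   `tst_min`, `sol_min`, `waso_min`.  If no step is scored asleep,
#'   SE and TST are 0 and SOL/WASO are `NA` (undefined), with a
#'   warning.
#' @export
#' @examples
#' sleep_wake_indices(c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
#'                    step_minutes = 1)
sleep_wake_indices <- function(asleep, step_minutes) {
  if (length(asleep) == 0L) stop("empty state sequence", call. = FALSE)
  if (!is.numeric(step_minutes) || step_minutes <= 0) {
    stop("`step_minutes` must be positive", call. = FALSE)
  }
  asleep <- as.logical(asleep)
  if (anyNA(asleep)) stop("state sequence contains NA", call. = FALSE)
  n <- length(asleep)
  n_sleep <- sum(asleep)
  if (n_sleep == 0L) {
    warning("no sleep scored: SOL and WASO are undefined")
    return(tibble::tibble(se = 0, tst_min = 0,
                          sol_min = NA_real_, waso_min = NA_real_))
  }
  onset <- which(asleep)[1]
  tibble::tibble(
    se = n_sleep / n,
    tst_min = n_sleep * step_minutes,
    sol_min = (onset - 1L) * step_minutes,
    waso_min = sum(!asleep[onset:n]) * step_minutes
  )
}

#' Full sleep-index set from a hypnogram
#'
#' Derives the whole index family the staging pipeline reports: the
#' binary sleep/wake indices (SE/TST/SOL/WASO, with sleep = any
#' non-Wake stage, 30-s resolution), stage durations in minutes, RNR
#' and SSI.  RNR and SSI are `NA` (rather than errors) when undefined,
#' so whole cohorts can be summarized without interruption.
#'
#' @param hyp A [hypnogram()].
#' @inheritParams rnr
#' @inheritParams ssi
#' @return A one-row tibble: `se`, `tst_min`, `sol_min`, `waso_min`,
#'   `wake_min`, `rem_min`, `light_min`, `deep_min`, `rnr`, `ssi`.
#' @export
#' @examples
#' sleep_indices(sample_hypnogram(840, seed = 1))
sleep_indices <- function(hyp, include_wake = FALSE,
                          count_wake_shifts = TRUE) {
  es <- epoch_seconds(hyp)
  mins <- stage_minutes(hyp)
  sw <- suppressWarnings(
    sleep_wake_indices(as.character(hyp) != "Wake", step_minutes = es / 60)
  )
  rnr_val <- tryCatch(rnr(hyp, include_wake = include_wake),
                      error = function(e) NA_real_)
  ssi_val <- tryCatch(ssi(hyp, count_wake_shifts = count_wake_shifts),
                      error = function(e) NA_real_)
  dplyr::bind_cols(
    sw,
    tibble::tibble(
      wake_min = mins[["Wake"]], rem_min = mins[["REM"]],
      light_min = mins[["Light"]], deep_min = mins[["Deep"]],
      rnr = rnr_val, ssi = ssi_val
    )
  )
}
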