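#' Four-stage sleep vocabulary
#'
#' The package scores sleep into four stages with a fixed index order:
#' Wake (1), REM (2), Light (3), Deep (4).  Light merges the classical
#' S1/S2 (or AASM N1/N2) stages and Deep merges S3/S4 (N3).  The order
#' matters: it is the row/column order of the transition matrix and the
#' band order of the emission model.
#'
#' @return Character vector of the four stage labels, in index order.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() {
  c("Wake", "REM", "Light", "Deep")
}

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of sleep-stage labels, one per
#' scoring epoch (30 s by default).  Internally it is a factor over the
#' four-stage vocabulary with an `epoch_seconds` attribute.
#'
#' @param stages Character or factor vector of stage labels drawn from
#'   [sleep_stages()].
#' @param epoch_seconds Positive epoch duration in seconds.
#' @return An object of class `hypnogram`.
#' @export
#' @examples
#' h <- hypnogram(c("Wake", "Wake", "Light", "Deep", "REM"))
#' as_tibble(h)
hypnogram <- function(stages, epoch_seconds = 30) {
  if (length(stages) == 0L) {
    stop("a hypnogram must contain at least one epoch", call. = FALSE)
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      !is.finite(epoch_seconds) || epoch_seconds <= 0) {
    stop("`epoch_seconds` must be a single positive number", call. = FALSE)
  }
  stages <- as.character(stages)
  bad <- setdiff(unique(stages[!is.na(stages)]), sleep_stages())
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(sleep_stages(), collapse = ", "),
         call. = FALSE)
  }
  structure(
    factor(stages, levels = sleep_stages()),
    epoch_seconds = as.numeric(epoch_seconds),
    class = c("hypnogram", "factor")
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  es <- epoch_seconds(x)
  cat(sprintf("<hypnogram> %d epochs x %g s (%.1f min)\n",
              length(x), es, length(x) * es / 60))
  counts <- table(factor(as.character(unclass_stages(x)),
                         levels = sleep_stages()))
  cat(paste(sprintf("%s: %d", names(counts), counts), collapse = "  "), "\n")
  invisible(x)
}

#' Epoch duration of a hypnogram
#'
#' @param x A `hypnogram`.
#' @return Epoch length in seconds.
#' @export
epoch_seconds <- function(x) {
  es <- attr(x, "epoch_seconds")
  if (is.null(es)) 30 else es
}

# character stage vector without dropping NA handling
unclass_stages <- function(x) {
  as.character(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tabular view of a hypnogram
#'
#' @param x A `hypnogram`.
#' @param ... Unused.
#' @return A tibble with `epoch` (0-based index), `onset_seconds`
#'   (epoch start, half-open interval \[onset, onset + epoch_seconds)),
#'   and `stage`.
#' @export
as_tibble.hypnogram <- function(x, ...) {
  es <- epoch_seconds(x)
  tibble::tibble(
    epoch = seq_along(x) - 1L,
    onset_seconds = (seq_along(x) - 1L) * es,
    stage = factor(as.character(x), levels = sleep_stages())
  )
}

#' Merge reference sleep-stage labels into the four-stage set
#'
#' Collapses classical R&K six-stage scoring (W, R, S1--S4) or AASM
#' five-stage scoring (W, R, N1--N3) onto the four stages used here:
#' S1/S2/N1/N2 become Light, S3/S4/N3 become Deep.  Sleep-EDFx-style
#' bare digit labels ("1".."4") are accepted as S1..S4.  Movement ("M")
#' and unscored ("?") epochs become `NA` so that evaluation can drop
#' them pairwise.
#'
#' @param labels Character vector of raw reference labels.
#' @param epoch_seconds Epoch duration of the reference scoring.
#' @return A [hypnogram()] of the same length; `NA` where the input was
#'   movement/unscored.
#' @export
#' @examples
#' merge_stages(c("W", "S1", "S2", "S3", "S4", "R"))
#' merge_stages(c("N1", "N2", "N3"))
merge_stages <- function(labels, epoch_seconds = 30) {
  if (length(labels) == 0L) {
    stop("empty label sequence", call. = FALSE)
  }
  labels <- toupper(trimws(as.character(labels)))
  map <- c(
    "W" = "Wake", "WAKE" = "Wake",
    "R" = "REM", "REM" = "REM",
    "S1" = "Light", "S2" = "Light", "S3" = "Deep", "S4" = "Deep",
    "N1" = "Light", "N2" = "Light", "N3" = "Deep",
    "1" = "Light", "2" = "Light", "3" = "Deep", "4" = "Deep",
    "M" = NA, "?" = NA
  )
  known <- labels %in% names(map)
  if (!all(known)) {
    stop("unrecognized stage label(s): ",
         paste(unique(labels[!known]), collapse = ", "), call. = FALSE)
  }
  merged <- unname(map[labels])
  out <- factor(merged, levels = sleep_stages())
  structure(out, epoch_seconds = as.numeric(epoch_seconds),
            class = c("hypnogram", "factor"))
}

#' Stage occupancy in minutes
#'
#' @param hyp A `hypnogram`.
#' @return Named numeric vector of minutes spent in each stage
#'   (NA-labelled epochs are excluded).
#' @export
stage_minutes <- function(hyp) {
  es <- epoch_seconds(hyp)
  counts <- table(factor(as.character(hyp), levels = sleep_stages()))
  stats::setNames(as.vector(counts) * es / 60, sleep_stages())
}
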