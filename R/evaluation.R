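#' One-vs-rest confusion counts for a sleep stage
#'
#' Treats `stage` as the positive class and everything else as
#' negative, comparing predicted and reference hypnograms epoch by
#' epoch.  Epoch pairs in which either label is `NA` (movement or
#' unscored reference epochs) are excluded before counting.
#'
#' @param pred Predicted [hypnogram()] (or character vector of stages).
#' @param truth Reference [hypnogram()] of the same length.
#' @param stage One of [sleep_stages()].
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
#' @examples
#' confusion_counts(hypnogram(rep("Wake", 4)),
#'                  hypnogram(c("Wake", "REM", "Light", "Deep")), "Wake")
confusion_counts <- function(pred, truth, stage) {
  stage <- match.arg(stage, sleep_stages())
  p <- as.character(pred)
  t_ <- as.character(truth)
  if (length(p) != length(t_)) {
    stop("predicted and reference hypnograms differ in length (",
         length(p), " vs ", length(t_), ")", call. = FALSE)
  }
  keep <- !is.na(p) & !is.na(t_)
  p <- p[keep]
  t_ <- t_[keep]
  c(tp = sum(p == stage & t_ == stage),
    fp = sum(p == stage & t_ != stage),
    fn = sum(p != stage & t_ == stage),
    tn = sum(p != stage & t_ != stage))
}

#' Per-stage classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 (all in percent) from
#' one-vs-rest counts: accuracy = (TP+TN)/(TP+FP+FN+TN), precision =
#' TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean of precision
#' and recall.  Ratios with a zero denominator are reported as `NA`
#' (never as 0, which would silently deflate averages).
#'
#' @param counts Named vector with elements `tp`, `fp`, `fn`, `tn`
#'   (as returned by [confusion_counts()]).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `f1` (percent).
#' @export
#' @examples
#' stage_metrics(c(tp = 80, fp = 20, fn = 10, tn = 890))
stage_metrics <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts))) {
    stop("`counts` must contain tp, fp, fn, tn", call. = FALSE)
  }
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  total <- tp + fp + fn + tn
  if (total <= 0) stop("no epochs to evaluate", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = 100 * (tp + tn) / total,
                 precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a predicted hypnogram against a reference
#'
#' Builds the per-stage evaluation report: one row per stage with
#' one-vs-rest confusion counts and accuracy/precision/recall/F1 in
#' percent, mirroring the standard four-stage benchmark table layout.
#'
#' @inheritParams confusion_counts
#' @return A tibble with a `stage` column followed by the
#'   [stage_metrics()] columns, four rows in stage order.
#' @export
#' @examples
#' truth <- sample_hypnogram(300, seed = 2)
#' pred <- truth
#' pred[1:30] <- "Wake"
#' evaluate_staging(pred, truth)
evaluate_staging <- function(pred, truth) {
  purrr::map_dfr(sleep_stages(), function(s) {
    dplyr::bind_cols(tibble::tibble(stage = s),
                     stage_metrics(confusion_counts(pred, truth, s)))
  })
}
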