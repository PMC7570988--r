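#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples, with the null
#' distribution computed *exactly* by dynamic programming over the
#' signed-rank generating function -- appropriate at small study sizes
#' (n = 10 here) where the normal approximation is poor.  Zero
#' differences are dropped (Wilcoxon's original convention); tied
#' absolute differences receive average ranks and the exact
#' distribution is computed conditionally on the observed ranks, so
#' ties are handled without approximation.  The reported statistic is
#' the classical T = min(W+, W-); the two-sided p-value doubles the
#' smaller tail of the exact distribution (capped at 1).
#'
#' @param paired_a,paired_b Numeric vectors of equal length; the test
#'   is on the differences `paired_a - paired_b`.
#' @return A one-row tibble: `statistic` (min of the two rank sums),
#'   `w_plus`, `p_value`, `n` (pairs remaining after zero removal).
#' @export
#' @examples
#' wilcoxon_exact(c(5, 7, 8, 9, 11, 13), c(4, 6, 7, 8, 10, 12))
wilcoxon_exact <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  d <- as.numeric(paired_a) - as.numeric(paired_b)
  if (anyNA(d)) stop("paired values contain NA", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  }
  if (n < 5L) {
    stop("fewer than 5 non-zero differences (n = ", n,
         "); the test is uninformative", call. = FALSE)
  }
  r <- rank(abs(d))  # average ranks on ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  # exact distribution of 2*W+ (doubling makes tied average ranks integer)
  s <- as.integer(round(2 * r))
  f <- c(1, numeric(sum(s)))
  for (si in s) {
    g <- f / 2
    shifted <- c(numeric(si), g[seq_len(length(f) - si)])
    f <- g + shifted
  }
  support <- seq_along(f) - 1L  # values of 2*W+
  p_le <- sum(f[support <= round(2 * w_plus) + 1e-9])
  p_ge <- sum(f[support >= round(2 * w_plus) - 1e-9])
  tibble::tibble(
    statistic = min(w_plus, w_minus),
    w_plus = w_plus,
    p_value = min(1, 2 * min(p_le, p_ge)),
    n = n
  )
}

#' Spearman rank correlation
#'
#' Nonparametric correlation between two equally long vectors: Pearson
#' correlation of the (average-tied) ranks, in \[-1, 1\].  Used for
#' relating subjective sleep-quality ratings to objective indices.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return Scalar rank correlation.
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # 1: invariant to monotone transforms
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs contain NA", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Split subjects into poor and good sleepers by PSQI
#'
#' Pittsburgh Sleep Quality Index above the cutoff (conventionally 5)
#' marks a poor sleeper.  The split is exhaustive and disjoint.
#'
#' @param records A data frame with a `psqi` column.
#' @param cutoff PSQI threshold, default 5; poor = `psqi > cutoff`.
#' @return A named list of two tibbles, `poor` and `good`.
#' @export
#' @examples
#' subj <- tibble::tibble(subject_id = 1:10, psqi = c(2:6, 6:10))
#' lengths(split_by_psqi(subj))
split_by_psqi <- function(records, cutoff = 5) {
  if (!"psqi" %in% names(records)) {
    stop("`records` must contain a `psqi` column", call. = FALSE)
  }
  if (cutoff < 0) stop("`cutoff` must be >= 0", call. = FALSE)
  list(
    poor = dplyr::filter(tibble::as_tibble(records), .data$psqi > cutoff),
    good = dplyr::filter(tibble::as_tibble(records), .data$psqi <= cutoff)
  )
}

signif_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare sleep indices between study conditions
#'
#' Builds the condition-comparison table of a within-subject mattress
#' (or any intervention) study: for every index column, the group mean
#' and SD under each condition, plus an exact paired Wilcoxon test
#' between the baseline condition and a comparison condition.  When
#' `compare` is `NULL` the comparison condition is chosen per index as
#' the non-baseline condition with the highest group mean (the
#' "condition with the highest score").  Subjects lacking a record
#' under either compared condition are excluded from the test with a
#' warning.  Degenerate tests (all differences zero, or too few
#' non-zero differences) yield `NA` p-values; the table still renders.
#'
#' @param records Data frame with `subject_id`, `condition`, and one
#'   numeric column per index (e.g. the output of
#'   [cohort_records()]).
#' @param indices Character vector of index columns to compare;
#'   default: every numeric column other than identifiers.
#' @param baseline Baseline condition label, default `"A"`.
#' @param compare Fixed comparison condition, or `NULL` for per-index
#'   selection.
#' @param p_adjust `"none"` (default, matching the single-comparison
#'   reporting convention) or `"holm"`.
#' @return A tibble with one row per index: `index`, `mean_<cond>` and
#'   `sd_<cond>` for each condition present, `compared`, `statistic`,
#'   `p_value`, `signif` (`*` p < 0.05, `**` p < 0.01).
#' @export
condition_comparison <- function(records, indices = NULL, baseline = "A",
                                 compare = NULL,
                                 p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  records <- tibble::as_tibble(records)
  if (!all(c("subject_id", "condition") %in% names(records))) {
    stop("`records` must contain subject_id and condition columns",
         call. = FALSE)
  }
  conds <- unique(as.character(records$condition))
  if (!baseline %in% conds) {
    stop("baseline condition '", baseline, "' not present", call. = FALSE)
  }
  if (length(conds) < 2L) {
    stop("need at least two conditions to compare", call. = FALSE)
  }
  if (is.null(indices)) {
    num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
    indices <- setdiff(num_cols, c("subject_id", "psqi"))
  }
  if (length(indices) == 0L) stop("no index columns found", call. = FALSE)

  rows <- purrr::map_dfr(indices, function(ix) {
    vals <- records[, c("subject_id", "condition", ix)]
    names(vals)[3] <- "value"
    summ <- vals |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                       sd = stats::sd(.data$value, na.rm = TRUE),
                       .groups = "drop")
    candidates <- setdiff(conds, baseline)
    cmp <- if (is.null(compare)) {
      cs <- summ[summ$condition %in% candidates, ]
      as.character(cs$condition[which.max(cs$mean)])
    } else {
      compare
    }
    wide <- vals |>
      dplyr::filter(.data$condition %in% c(baseline, cmp)) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "value")
    complete <- stats::complete.cases(wide[, c(baseline, cmp)])
    if (any(!complete)) {
      warning(sum(!complete), " unpaired subject(s) excluded for index '",
              ix, "'", call. = FALSE)
      wide <- wide[complete, ]
    }
    test <- tryCatch(
      wilcoxon_exact(wide[[baseline]], wide[[cmp]]),
      error = function(e) tibble::tibble(statistic = NA_real_,
                                         w_plus = NA_real_,
                                         p_value = NA_real_,
                                         n = nrow(wide))
    )
    stats_wide <- summ |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = c("mean", "sd"))
    dplyr::bind_cols(
      tibble::tibble(index = ix), stats_wide,
      tibble::tibble(compared = cmp, statistic = test$statistic,
                     p_value = test$p_value)
    )
  })
  if (p_adjust == "holm") {
    rows$p_value <- stats::p.adjust(rows$p_value, method = "holm")
  }
  rows$signif <- signif_code(rows$p_value)
  rows
}
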