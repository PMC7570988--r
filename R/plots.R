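#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hypnogram
#'
#' Classical hypnogram step plot: time on the x axis, stages on the y
#' axis ordered Wake (top) to Deep (bottom), REM emphasized as is
#' customary in sleep charts.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypnogram <- function(object, ...) {
  df <- as_tibble(object)
  df$hours <- df$onset_seconds / 3600
  df$level <- 5L - as.integer(df$stage)  # Wake on top
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$level)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_point(
      data = df[!is.na(df$stage) & df$stage == "REM", ],
      colour = "red", size = 0.6
    ) +
    ggplot2::scale_y_continuous(breaks = 4:1, labels = sleep_stages(),
                                limits = c(0.5, 4.5)) +
    ggplot2::labs(x = "Time (h)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Plot the EM log-likelihood trace of a fitted sleep HMM
#'
#' @param object A `sleep_hmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sleep_hmm_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik),
                       loglik = object$loglik)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-epoch relative band powers
#'
#' @param features A [band_powers()] tibble.
#' @return A ggplot object.
#' @export
plot_band_powers <- function(features) {
  long <- tidyr::pivot_longer(features, dplyr::starts_with("p_"),
                              names_to = "band", values_to = "power")
  long$band <- factor(long$band,
                      levels = paste0("p_", tolower(sleep_stages())),
                      labels = sleep_stages())
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$band,
                                     fill = .data$power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Epoch", y = "Band", fill = "Relative\npower") +
    ggplot2::theme_minimal()
}
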