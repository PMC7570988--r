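#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a fitted sleep HMM
#'
#' One row per scalar parameter, in long format: initial probabilities
#' (`term = "pi"`, keyed by `stage`), transitions (`term = "transition"`,
#' keyed by `stage` -> `to`), and emission means/sds (`term = "mean"` /
#' `"sd"`, keyed by `stage` and `band`).
#'
#' @param x A `sleep_hmm_fit` (or bare `sleep_hmm` parameter set).
#' @param ... Unused.
#' @return A tibble with columns `term`, `stage`, `to`, `band`,
#'   `estimate`.
#' @export
tidy.sleep_hmm_fit <- function(x, ...) {
  tidy.sleep_hmm(x$params)
}

#' @rdname tidy.sleep_hmm_fit
#' @export
tidy.sleep_hmm <- function(x, ...) {
  stages <- sleep_stages()
  dplyr::bind_rows(
    tibble::tibble(term = "pi", stage = stages, to = NA_character_,
                   band = NA_character_, estimate = unname(x$pi)),
    tidyr::expand_grid(stage = stages, to = stages) |>
      dplyr::mutate(term = "transition", band = NA_character_,
                    estimate = as.vector(t(x$Q))) |>
      dplyr::select("term", "stage", "to", "band", "estimate"),
    tidyr::expand_grid(stage = stages, band = stages) |>
      dplyr::mutate(term = "mean", to = NA_character_,
                    estimate = as.vector(t(x$mu))) |>
      dplyr::select("term", "stage", "to", "band", "estimate"),
    tidyr::expand_grid(stage = stages, band = stages) |>
      dplyr::mutate(term = "sd", to = NA_character_,
                    estimate = as.vector(t(x$sigma))) |>
      dplyr::select("term", "stage", "to", "band", "estimate")
  )
}

#' One-row summary of a fitted sleep HMM
#'
#' @param x A `sleep_hmm_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik` (final), `n_iter`, `converged`,
#'   `n_epochs`.
#' @export
glance.sleep_hmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik[length(x$loglik)], n_iter = x$n_iter,
                 converged = x$converged, n_epochs = x$n_epochs)
}
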