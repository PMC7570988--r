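#' Stage-associated EEG frequency bands
#'
#' The four bands whose relative powers drive the stager, in stage
#' order: Wake 35--50 Hz (high beta/gamma), REM 20--30 Hz (beta),
#' Light 10.15--15.75 Hz (sigma/spindle range), Deep 1--3 Hz (delta).
#'
#' @return A tibble with columns `stage`, `low_hz`, `high_hz`.
#' @export
#' @examples
#' sleep_bands()
sleep_bands <- function() {
  tibble::tibble(
    stage = sleep_stages(),
    low_hz = c(35, 20, 10.15, 1),
    high_hz = c(50, 30, 15.75, 3)
  )
}

check_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("stage", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz >= bands$high_hz)) {
    stop("each band must have low_hz < high_hz", call. = FALSE)
  }
  bands
}

#' Segment a signal into fixed-length epochs
#'
#' Cuts a continuous single-channel signal into non-overlapping epochs
#' of `epoch_seconds`; a trailing partial epoch is dropped.
#'
#' @param signal Numeric sample vector.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @return A numeric matrix, one row per epoch.
#' @export
#' @examples
#' dim(segment_epochs(rnorm(100 * 90), 100))  # 3 epochs x 3000 samples
segment_epochs <- function(signal, sampling_rate_hz, epoch_seconds = 30) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be positive", call. = FALSE)
  }
  if (!is.numeric(epoch_seconds) || epoch_seconds <= 0) {
    stop("`epoch_seconds` must be positive", call. = FALSE)
  }
  spe <- round(sampling_rate_hz * epoch_seconds)
  n_epochs <- floor(length(signal) / spe)
  if (n_epochs < 1L) {
    stop("signal shorter than one epoch (", spe, " samples needed, ",
         length(signal), " given)", call. = FALSE)
  }
  m <- matrix(signal[seq_len(n_epochs * spe)], nrow = n_epochs,
              ncol = spe, byrow = TRUE)
  attr(m, "sampling_rate_hz") <- sampling_rate_hz
  attr(m, "epoch_seconds") <- epoch_seconds
  m
}

# Frequency-domain weights for complex Morlet filtering of one band.
#
# For each centre frequency c on a 0.5 Hz grid across the band, the
# squared gain of a Morlet wavelet (spectral sd = c / n_cycles) is
# evaluated on the FFT bin grid and normalized to unit white-noise
# power gain, so every centre reports a local average of the power
# spectral density.  Averaging centres and multiplying by the band
# width turns that density into band power, directly comparable to
# integrating a periodogram over the band.
morlet_band_weights <- function(n, sampling_rate_hz, low, high,
                                n_cycles = 7, step_hz = 0.5) {
  freqs <- (seq_len(n %/% 2 + 1) - 1) * sampling_rate_hz / n
  centers <- unique(c(seq(low, high, by = step_hz), high))
  w <- numeric(length(freqs))
  for (c0 in centers) {
    sd_f <- c0 / n_cycles
    g2 <- exp(-(freqs - c0)^2 / sd_f^2)
    w <- w + g2 / sum(g2)
  }
  w / length(centers) * (high - low)
}

#' Relative band powers per epoch
#'
#' For each epoch and each band, the band power is the mean squared
#' amplitude of the band-filtered epoch, realized as complex Morlet
#' wavelet filtering averaged over a grid of centre frequencies
#' spanning the band (computed in the frequency domain via Parseval's
#' identity).  Rows are normalized to sum to one, so each row lives on
#' the probability simplex the emission model expects.
#'
#' @param epochs Epoch matrix from [segment_epochs()], or a numeric
#'   vector holding a single epoch.
#' @param sampling_rate_hz Sampling rate; required if `epochs` carries
#'   no `sampling_rate_hz` attribute.  Must be at least twice the
#'   highest band edge.
#' @param bands Band definition tibble, defaults to [sleep_bands()].
#' @param n_cycles Morlet wavelet width in cycles (default 7).
#' @return A tibble with `epoch` (0-based) and one `p_<stage>` column
#'   per band, rows summing to 1.
#' @export
#' @examples
#' sig <- sin(2 * pi * 25 * seq(0, 30, by = 1 / 100))  # pure 25 Hz tone
#' band_powers(segment_epochs(sig, 100), 100)
band_powers <- function(epochs, sampling_rate_hz = NULL,
                        bands = sleep_bands(), n_cycles = 7) {
  if (is.null(dim(epochs))) epochs <- matrix(epochs, nrow = 1L)
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- attr(epochs, "sampling_rate_hz")
  }
  if (is.null(sampling_rate_hz)) {
    stop("`sampling_rate_hz` must be supplied", call. = FALSE)
  }
  bands <- check_bands(bands)
  if (sampling_rate_hz < 2 * max(bands$high_hz)) {
    stop("sampling rate ", sampling_rate_hz, " Hz is below the Nyquist ",
         "requirement of ", 2 * max(bands$high_hz), " Hz", call. = FALSE)
  }
  n <- ncol(epochs)
  w <- vapply(seq_len(nrow(bands)), function(b) {
    morlet_band_weights(n, sampling_rate_hz, bands$low_hz[b],
                        bands$high_hz[b], n_cycles = n_cycles)
  }, numeric(n %/% 2 + 1))
  pow <- matrix(NA_real_, nrow(epochs), nrow(bands))
  idx <- seq_len(n %/% 2 + 1)
  for (i in seq_len(nrow(epochs))) {
    spec <- Mod(stats::fft(epochs[i, ]))^2
    pow[i, ] <- as.vector(spec[idx] %*% w)
  }
  rel <- pow / rowSums(pow)
  out <- tibble::as_tibble(as.data.frame(rel))
  names(out) <- paste0("p_", tolower(bands$stage))
  out <- dplyr::bind_cols(tibble::tibble(epoch = seq_len(nrow(rel)) - 1L), out)
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  attr(out, "epoch_seconds") <- attr(epochs, "epoch_seconds")
  out
}

# Accept either a band_powers() tibble or a bare numeric matrix and
# return the n_epochs x 4 feature matrix the HMM consumes.
as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (ncol(features) != 4L) {
      stop("feature matrix must have 4 columns (one per stage band)",
           call. = FALSE)
    }
    return(features)
  }
  if (is.data.frame(features)) {
    cols <- paste0("p_", tolower(sleep_stages()))
    if (!all(cols %in% names(features))) {
      stop("feature data frame must contain columns ",
           paste(cols, collapse = ", "), call. = FALSE)
    }
    return(as.matrix(features[, cols]))
  }
  stop("`features` must be a matrix or a band-power data frame",
       call. = FALSE)
}
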