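#' Sample a hypnogram from a stage Markov chain
#'
#' Draws a stage sequence from the first-order Markov chain with
#' initial distribution `pi` and transition matrix `Q` (defaults: the
#' canonical stager initialization, i.e. nights start awake and follow
#' the literature-derived overnight dynamics).  Deterministic given
#' the seed.
#'
#' @param n_epochs Number of epochs (>= 2).
#' @param pi Initial stage distribution (length 4).
#' @param Q 4x4 row-stochastic transition matrix.
#' @param epoch_seconds Epoch duration, default 30.
#' @param seed Integer seed (mandatory: every generated artifact is a
#'   deterministic function of its parameters and seed).
#' @return A [hypnogram()].
#' @export
#' @examples
#' sample_hypnogram(10, seed = 1)
sample_hypnogram <- function(n_epochs, pi = hmm_init_params()$pi,
                             Q = hmm_init_params()$Q, epoch_seconds = 30,
                             seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_epochs < 2L) stop("`n_epochs` must be >= 2", call. = FALSE)
  set.seed(seed)
  cpi <- cumsum(pi)
  cQ <- t(apply(Q, 1, cumsum))
  u <- stats::runif(n_epochs)
  states <- integer(n_epochs)
  states[1] <- findInterval(u[1], cpi, left.open = TRUE) + 1L
  for (t in seq_len(n_epochs - 1L) + 1L) {
    states[t] <- findInterval(u[t], cQ[states[t - 1L], ],
                              left.open = TRUE) + 1L
  }
  hypnogram(sleep_stages()[pmin(states, 4L)], epoch_seconds = epoch_seconds)
}

#' Simulate epoch feature vectors from the emission model
#'
#' Draws one 4-band feature vector per epoch from the stage-conditional
#' diagonal Gaussian emission model -- the exact generative model the
#' HMM assumes, useful for parameter-recovery experiments.
#'
#' @param hyp A [hypnogram()] supplying the stage per epoch.
#' @param params A [hmm_params()] object; `mu` and `sigma` are used.
#' @param seed Integer seed.
#' @return An n x 4 numeric matrix of features (not simplex-normalized;
#'   this is the raw emission model).
#' @export
simulate_features <- function(hyp, params = hmm_init_params(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  params <- as_hmm_params(params)
  set.seed(seed)
  idx <- as.integer(unclass(hyp))
  n <- length(idx)
  noise <- matrix(stats::rnorm(n * 4L), n, 4L)
  params$mu[idx, , drop = FALSE] + noise * params$sigma[idx, , drop = FALSE]
}

# Gaussian band-limited noise, one epoch, via frequency-domain shaping;
# returned with unit sample variance.
band_noise <- function(n, sampling_rate_hz, low, high) {
  freqs <- (seq_len(n %/% 2) - 1) * sampling_rate_hz / n  # excl. Nyquist
  bins <- which(freqs >= low & freqs <= high & freqs > 0)
  if (length(bins) < 2L) {
    stop("band ", low, "-", high, " Hz holds fewer than 2 FFT bins",
         call. = FALSE)
  }
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  z <- complex(real = stats::rnorm(length(bins)),
               imaginary = stats::rnorm(length(bins)))
  spec[bins] <- z
  spec[n - bins + 2L] <- Conj(z)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize single-channel EEG from a hypnogram
#'
#' Emulates the band-power structure the stager consumes: each epoch
#' is a sum of four band-limited Gaussian noise components whose
#' relative powers are drawn from a Gaussian around the stage's
#' emission-mean row (clipped at zero and renormalized to the
#' simplex), then scaled to unit total variance.  Signal continuity at
#' epoch boundaries is not guaranteed -- the generator reproduces the
#' band-power statistics of sleep EEG, not its waveform morphology
#' (no spindles or K-complexes).
#'
#' @param hyp A [hypnogram()].
#' @param sampling_rate_hz Sampling rate, >= 100 Hz.
#' @param mu 4x4 stage-by-band relative-power means, default the
#'   canonical 0.7/0.1 structure.
#' @param sd Scatter of the per-epoch relative powers around `mu`
#'   (scalar).  The default 0.15 puts the stage clusters four standard
#'   deviations apart (0.7 - 0.1 = 4 x 0.15), the separation regime
#'   the validation suites assume; 0 gives deterministic powers.
#' @param bands Band definitions, default [sleep_bands()].
#' @param seed Integer seed.
#' @return Numeric vector of length `n_epochs * epoch_seconds * rate`.
#' @export
synthesize_eeg <- function(hyp, sampling_rate_hz = 100,
                           mu = hmm_init_params()$mu, sd = 0.15,
                           bands = sleep_bands(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (sampling_rate_hz < 2 * max(bands$high_hz)) {
    stop("sampling rate must be at least ", 2 * max(bands$high_hz), " Hz",
         call. = FALSE)
  }
  set.seed(seed)
  es <- epoch_seconds(hyp)
  n <- round(sampling_rate_hz * es)
  idx <- as.integer(unclass(hyp))
  out <- numeric(length(idx) * n)
  for (e in seq_along(idx)) {
    p <- pmax(stats::rnorm(4L, mu[idx[e], ], sd), 0)
    if (sum(p) <= 0) p <- mu[idx[e], ]
    p <- p / sum(p)
    x <- numeric(n)
    for (b in 1:4) {
      if (p[b] > 0) {
        x <- x + sqrt(p[b]) *
          band_noise(n, sampling_rate_hz, bands$low_hz[b], bands$high_hz[b])
      }
    }
    out[(e - 1L) * n + seq_len(n)] <- x / stats::sd(x)
  }
  out
}

#' Synthesize per-minute actigraphy counts from a hypnogram
#'
#' Per-minute activity counts drawn from a Poisson distribution whose
#' mean is `wake_rate` during minutes whose first epoch is Wake and
#' `sleep_rate` otherwise.  Counts are non-negative integers, as
#' actigraphy software exports them.
#'
#' @param hyp A [hypnogram()].
#' @param wake_rate Mean counts per wake minute (must exceed
#'   `sleep_rate`); default 150.
#' @param sleep_rate Mean counts per sleep minute, default 5.
#' @param seed Integer seed.
#' @return A tibble with `minute` (0-based), `counts`, and the
#'   ground-truth `wake` flag; one row per complete minute of the
#'   hypnogram.
#' @export
synthesize_actigraphy <- function(hyp, wake_rate = 150, sleep_rate = 5,
                                  seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!(wake_rate > sleep_rate) || sleep_rate < 0) {
    stop("need wake_rate > sleep_rate >= 0", call. = FALSE)
  }
  set.seed(seed)
  es <- epoch_seconds(hyp)
  n_min <- floor(length(hyp) * es / 60)
  if (n_min < 1L) stop("hypnogram shorter than one minute", call. = FALSE)
  first_epoch <- floor((seq_len(n_min) - 1L) * 60 / es) + 1L
  wake <- as.character(hyp)[first_epoch] == "Wake"
  counts <- stats::rpois(n_min, ifelse(wake, wake_rate, sleep_rate))
  tibble::tibble(minute = seq_len(n_min) - 1L, counts = counts, wake = wake)
}

# Convert `minutes` worth of epochs from stage `from` to stage `to`,
# run by run in order of appearance (partial final run), so injected
# condition effects are exactly known in minutes.
shift_stage_minutes <- function(hyp, from, to, minutes) {
  if (minutes <= 0) return(hyp)
  es <- epoch_seconds(hyp)
  need <- round(minutes * 60 / es)
  stages <- as.character(hyp)
  r <- rle(stages)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values == from)) {
    if (need <= 0) break
    take <- min(need, r$lengths[k])
    stages[starts[k]:(starts[k] + take - 1L)] <- to
    need <- need - take
  }
  if (need > 0) {
    warning("only ", minutes - need * es / 60, " of ", minutes,
            " requested minutes could be converted from ", from,
            call. = FALSE)
  }
  hypnogram(stages, epoch_seconds = es)
}

default_psqi <- function(n_subjects) {
  # emulates the studied cohort: mean ~5.6, range 2-10, half above 5
  base <- c(2L, 3L, 4L, 4L, 5L, 6L, 7L, 7L, 8L, 10L)
  rep_len(base, n_subjects)
}

#' Generate a synthetic within-subject sleep study
#'
#' Builds a full cohort in the three-condition, ten-subject design the
#' analysis layer expects: for every subject and condition a synthetic
#' night (ground-truth hypnogram sampled from the canonical stage
#' chain, per-minute actigraphy counts, subjective depth/length
#' ratings), with condition effects injected as exactly known stage
#' conversions -- `rem_boost_min` minutes of Light converted to REM
#' and `deep_shift_min` minutes moved between Light and Deep (negative
#' values move Deep to Light).  Defaults reproduce the effect
#' direction of the studied intervention: longer REM and slightly less
#' Deep under the customized conditions, PSQI values splitting the
#' cohort into five poor and five good sleepers.
#'
#' EEG is not materialized here (a 10 x 3 cohort of full-night signals
#' is large); synthesize it per night with [synthesize_eeg()] on the
#' hypnograms in the result.
#'
#' @param n_subjects Number of subjects, default 10.
#' @param conditions Condition labels, subset of `c("A", "S", "SH")`.
#' @param rem_boost_min Named vector of REM minutes added per
#'   condition (Light converted to REM).
#' @param deep_shift_min Named vector of Deep-minute changes per
#'   condition (negative: Deep converted to Light).
#' @param psqi Integer PSQI per subject (0-21); default emulates the
#'   studied cohort (mean 5.6, range 2-10, five poor sleepers).
#' @param subjective_depth_mean,subjective_length_mean Named vectors of
#'   mean subjective ratings (1-7 scale) per condition; defaults follow
#'   the reported pattern (customization felt worse subjectively).
#' @param n_epochs Epochs per night, default 840 (7 h of 30-s epochs).
#' @param epoch_seconds Epoch duration, default 30.
#' @param wake_rate,sleep_rate Actigraphy Poisson means, see
#'   [synthesize_actigraphy()].
#' @param seed Integer seed.
#' @return An object of class `sleep_cohort`: list with `subjects`
#'   (subject_id, psqi, sleeper group), `nights` (one row per subject
#'   x condition with list-columns `hypnogram` and `activity`,
#'   subjective ratings, and per-night seeds), and `records` (wide
#'   index table from [cohort_records()], ready for
#'   [condition_comparison()]).
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(seed = 42)
#' condition_comparison(coh$records, indices = c("rem_min", "rnr"))
#' }
generate_cohort <- function(n_subjects = 10,
                            conditions = c("A", "S", "SH"),
                            rem_boost_min = c(A = 0, S = 5, SH = 13),
                            deep_shift_min = c(A = 0, S = -8, SH = -8),
                            psqi = default_psqi(n_subjects),
                            subjective_depth_mean = c(A = 5.0, S = 4.7,
                                                      SH = 4.1),
                            subjective_length_mean = c(A = 5.2, S = 4.8,
                                                       SH = 3.6),
                            n_epochs = 840, epoch_seconds = 30,
                            wake_rate = 150, sleep_rate = 5, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(length(psqi) == n_subjects, all(psqi >= 0 & psqi <= 21))
  conditions <- match.arg(conditions, c("A", "S", "SH"), several.ok = TRUE)
  set.seed(seed)
  night_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, n_subjects * length(conditions) * 2),
    nrow = n_subjects * length(conditions)
  )
  subj_ratings_sd <- 1.3

  grid <- tidyr::expand_grid(subject_id = seq_len(n_subjects),
                             condition = conditions)
  nights <- purrr::pmap_dfr(
    list(grid$subject_id, grid$condition, seq_len(nrow(grid))),
    function(sid, cond, row) {
      hs <- night_seeds[row, 1]
      hyp <- sample_hypnogram(n_epochs, epoch_seconds = epoch_seconds,
                              seed = hs)
      boost <- rem_boost_min[[cond]]
      if (boost > 0) hyp <- shift_stage_minutes(hyp, "Light", "REM", boost)
      dshift <- deep_shift_min[[cond]]
      if (dshift > 0) {
        hyp <- shift_stage_minutes(hyp, "Light", "Deep", dshift)
      } else if (dshift < 0) {
        hyp <- shift_stage_minutes(hyp, "Deep", "Light", -dshift)
      }
      act <- synthesize_actigraphy(hyp, wake_rate = wake_rate,
                                   sleep_rate = sleep_rate,
                                   seed = night_seeds[row, 2])
      set.seed(night_seeds[row, 2] %% 1000000L + row)
      depth <- pmin(pmax(round(stats::rnorm(
        1, subjective_depth_mean[[cond]], subj_ratings_sd)), 1), 7)
      len <- pmin(pmax(round(stats::rnorm(
        1, subjective_length_mean[[cond]], subj_ratings_sd)), 1), 7)
      tibble::tibble(subject_id = sid, condition = cond,
                     hypnogram = list(hyp), activity = list(act),
                     subjective_depth = depth, subjective_length = len,
                     hyp_seed = hs)
    })

  subjects <- tibble::tibble(
    subject_id = seq_len(n_subjects), psqi = as.integer(psqi),
    sleeper = ifelse(psqi > 5, "poor", "good")
  )
  cohort <- structure(list(subjects = subjects, nights = nights,
                           records = NULL),
                      class = "sleep_cohort")
  cohort$records <- cohort_records(cohort)
  cohort
}

#' Wide per-night index table of a synthetic cohort
#'
#' Flattens a [generate_cohort()] result into one row per subject and
#' condition: subjective ratings, the full hypnogram-derived index set
#' (from the ground-truth hypnogram), and the actigraphy-derived
#' SE/TST/SOL/WASO obtained by Sadeh-scoring the synthetic counts
#' (prefixed `act_`).  This is the `records` layout
#' [condition_comparison()] consumes.
#'
#' @param cohort A `sleep_cohort`.
#' @return A tibble, one row per night.
#' @export
cohort_records <- function(cohort) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  idx <- purrr::map_dfr(seq_len(nrow(cohort$nights)), function(i) {
    night <- cohort$nights[i, ]
    hyp_idx <- sleep_indices(night$hypnogram[[1]])
    act <- night$activity[[1]]
    act_sw <- sleep_wake_indices(sadeh_scores(act$counts)$asleep,
                                 step_minutes = 1)
    names(act_sw) <- paste0("act_", names(act_sw))
    dplyr::bind_cols(
      tibble::tibble(subject_id = night$subject_id,
                     condition = night$condition,
                     subjective_depth = night$subjective_depth,
                     subjective_length = night$subjective_length),
      hyp_idx, act_sw
    )
  })
  dplyr::left_join(idx, cohort$subjects, by = "subject_id")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  cat(sprintf("<sleep_cohort> %d subjects x %d condition(s), %d nights\n",
              nrow(x$subjects),
              length(unique(x$nights$condition)), nrow(x$nights)))
  invisible(x)
}
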