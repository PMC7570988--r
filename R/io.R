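pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write signals to an EDF file
#'
#' Minimal European Data Format writer (16-bit integer samples, one
#' fixed sampling rate per channel) sufficient for round-tripping
#' synthetic EEG.  Samples are linearly quantized between the signal's
#' physical minimum and maximum onto the full 16-bit digital range, so
#' re-reading reproduces the input to within one quantization step.
#'
#' @param signals Named list of numeric vectors (channel label ->
#'   samples), or a single numeric vector.
#' @param path Output file path.
#' @param sampling_rate_hz Sampling rate in Hz (scalar, shared by all
#'   channels; must make an integer number of samples per one-second
#'   record).
#' @param channel Label used when `signals` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, sampling_rate_hz, channel = "EEG") {
  if (is.numeric(signals)) {
    signals <- stats::setNames(list(signals), channel)
  }
  stopifnot(is.list(signals), length(signals) >= 1L,
            !is.null(names(signals)))
  spr <- round(sampling_rate_hz)  # samples per 1-s record
  if (abs(spr - sampling_rate_hz) > 1e-9) {
    stop("`sampling_rate_hz` must be an integer for 1-s EDF records",
         call. = FALSE)
  }
  n_rec <- min(vapply(signals, function(s) floor(length(s) / spr),
                      numeric(1)))
  if (n_rec < 1L) stop("signals shorter than one 1-s record", call. = FALSE)
  ns <- length(signals)
  dig_min <- -32768L; dig_max <- 32767L
  phys <- lapply(signals, function(s) {
    r <- range(s[seq_len(n_rec * spr)])
    if (diff(r) == 0) r <- r + c(-1, 1)
    r
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic subject", 80),
    pad_field("synthetic recording", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4)
  )
  field <- function(f, width) {
    paste(vapply(seq_len(ns), function(i) pad_field(f(i), width),
                 character(1)), collapse = "")
  }
  hdr <- paste0(
    hdr,
    field(function(i) names(signals)[i], 16),
    field(function(i) "", 80),
    field(function(i) "uV", 8),
    field(function(i) formatC(phys[[i]][1], digits = 6, format = "g"), 8),
    field(function(i) formatC(phys[[i]][2], digits = 6, format = "g"), 8),
    field(function(i) dig_min, 8),
    field(function(i) dig_max, 8),
    field(function(i) "", 80),
    field(function(i) spr, 8),
    field(function(i) "", 32)
  )
  writeChar(hdr, con, eos = NULL)
  digital <- lapply(seq_len(ns), function(i) {
    s <- signals[[i]][seq_len(n_rec * spr)]
    p <- phys[[i]]
    as.integer(round((s - p[1]) / (p[2] - p[1]) *
                       (dig_max - dig_min) + dig_min))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- (r - 1L) * spr + seq_len(spr)
      writeBin(digital[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  h <- list(version = rd(8), patient = rd(80), recording = rd(80),
            startdate = rd(8), starttime = rd(8),
            header_bytes = as.integer(rd(8)), reserved = rd(44),
            n_records = as.integer(rd(8)),
            record_seconds = as.numeric(rd(8)), ns = as.integer(rd(4)))
  ns <- h$ns
  per <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  h$labels <- per(16); per(80)
  h$phys_dim <- per(8)
  h$phys_min <- as.numeric(per(8)); h$phys_max <- as.numeric(per(8))
  h$dig_min <- as.numeric(per(8)); h$dig_max <- as.numeric(per(8))
  per(80)
  h$samples_per_record <- as.integer(per(8)); per(32)
  h
}

#' Read one channel from an EDF file
#'
#' Parses the EDF header, validates that the file holds exactly the
#' declared number of data records (truncated files are rejected), and
#' returns the requested channel.  Channel matching is
#' case-insensitive on the trimmed label.
#'
#' @param path EDF file path.
#' @param channel Channel label (e.g. `"Fpz-Cz"`); default: the first
#'   channel.
#' @return A list of class `edf_recording`: `signal` (numeric),
#'   `sampling_rate_hz`, `channel`, `labels` (all channels present),
#'   `n_seconds`.
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (is.na(h$ns) || h$ns < 1L) stop("malformed EDF header", call. = FALSE)
  expected <- h$header_bytes +
    h$n_records * sum(h$samples_per_record) * 2
  actual <- file.size(path)
  if (is.na(h$n_records) || actual < expected) {
    stop("truncated or malformed EDF: expected ", expected, " bytes, found ",
         actual, call. = FALSE)
  }
  labels <- trimws(h$labels)
  if (is.null(channel)) channel <- labels[1]
  ci <- match(tolower(trimws(channel)), tolower(labels))
  if (is.na(ci)) {
    stop("channel '", channel, "' not found; available: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  rec_len <- sum(h$samples_per_record)
  raw <- readBin(con, "integer", n = h$n_records * rec_len, size = 2L,
                 endian = "little")
  offsets <- c(0L, cumsum(h$samples_per_record))
  spr <- h$samples_per_record[ci]
  sel <- as.vector(vapply(seq_len(h$n_records), function(r) {
    (r - 1L) * rec_len + offsets[ci] + seq_len(spr)
  }, integer(spr)))
  dig <- raw[sel]
  phys <- h$phys_min[ci] + (dig - h$dig_min[ci]) *
    (h$phys_max[ci] - h$phys_min[ci]) / (h$dig_max[ci] - h$dig_min[ci])
  structure(list(signal = phys,
                 sampling_rate_hz = spr / h$record_seconds,
                 channel = labels[ci], labels = labels,
                 n_seconds = h$n_records * h$record_seconds),
            class = "edf_recording")
}

#' @export
print.edf_recording <- function(x, ...) {
  cat(sprintf("<edf_recording> channel %s, %g Hz, %g s (%d samples)\n",
              x$channel, x$sampling_rate_hz, x$n_seconds, length(x$signal)))
  invisible(x)
}

stage_codes <- c(Wake = "W", REM = "R", Light = "L", Deep = "D")

#' Write a hypnogram to CSV
#'
#' Columns: `epoch_index` (0-based), `onset_seconds`, `stage` coded
#' W/R/L/D.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  df <- as_tibble(hyp)
  out <- tibble::tibble(epoch_index = df$epoch,
                        onset_seconds = df$onset_seconds,
                        stage = unname(stage_codes[as.character(df$stage)]))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' @param path CSV written by [write_hypnogram_csv()] (columns
#'   `epoch_index`, `onset_seconds`, `stage` in W/R/L/D).
#' @return A [hypnogram()]; epoch duration inferred from the onset
#'   spacing (30 s for a single-epoch file).
#' @export
read_hypnogram_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("epoch_index", "onset_seconds", "stage")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$epoch_index), ]
  es <- if (nrow(df) > 1L) diff(df$onset_seconds[1:2]) else 30
  rev_codes <- stats::setNames(names(stage_codes), stage_codes)
  labs <- rev_codes[as.character(df$stage)]
  if (anyNA(labs)) {
    stop("unknown stage code(s): ",
         paste(unique(df$stage[is.na(labs)]), collapse = ", "),
         call. = FALSE)
  }
  hypnogram(unname(labs), epoch_seconds = es)
}

#' Read a reference hypnogram from an annotation CSV
#'
#' Expands variable-duration stage annotations (columns
#' `onset_seconds`, `duration_seconds`, `stage`) into a per-epoch raw
#' label sequence over the classical alphabet
#' `{W, R, 1, 2, 3, 4, M, ?}` (or N1/N2/N3 and S1--S4 synonyms).
#' Movement/unscored labels are retained so evaluation can exclude
#' them pairwise; pass the result to [merge_stages()] to obtain a
#' four-stage hypnogram.  Overlapping or non-contiguous annotations
#' are rejected.
#'
#' @param path Annotation CSV path.
#' @param epoch_seconds Epoch grid for the expansion, default 30.
#' @return Character vector of raw per-epoch labels.
#' @export
read_reference_hypnogram <- function(path, epoch_seconds = 30) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("onset_seconds", "duration_seconds", "stage")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$onset_seconds), ]
  ends <- df$onset_seconds + df$duration_seconds
  if (nrow(df) > 1L &&
      any(df$onset_seconds[-1] < ends[-nrow(df)] - 1e-9)) {
    stop("overlapping annotations", call. = FALSE)
  }
  alphabet <- c("W", "R", "1", "2", "3", "4", "M", "?",
                "S1", "S2", "S3", "S4", "N1", "N2", "N3")
  labs <- toupper(trimws(as.character(df$stage)))
  if (!all(labs %in% alphabet)) {
    stop("labels outside the reference alphabet: ",
         paste(unique(labs[!labs %in% alphabet]), collapse = ", "),
         call. = FALSE)
  }
  n_ep <- floor(df$duration_seconds / epoch_seconds)
  if (any(abs(df$duration_seconds - n_ep * epoch_seconds) > 1e-9)) {
    stop("annotation durations must be multiples of ", epoch_seconds,
         " s", call. = FALSE)
  }
  rep(labs, times = n_ep)
}

#' Serialize HMM parameters to JSON
#'
#' Plain-text JSON with full floating-point precision, so a
#' write/read round trip is bit-exact.
#'
#' @param params A [hmm_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  params <- as_hmm_params(params)
  obj <- list(pi = unname(params$pi),
              Q = unname(params$Q),
              mu = unname(params$mu),
              sigma = unname(params$sigma))
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read HMM parameters from JSON
#'
#' @param path JSON file written by [write_params_json()].
#' @return A [hmm_params()] object.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_params(pi = obj$pi, Q = obj$Q, mu = obj$mu, sigma = obj$sigma)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [generate_cohort()] result as plain-text files:
#' per-night hypnogram CSVs and actigraphy-count CSVs, a subject
#' metadata CSV, the wide index table, and a manifest listing every
#' file with the seed of the night that produced it.  With
#' `eeg = TRUE` a full-night EDF is synthesized and written per night.
#'
#' @param cohort A `sleep_cohort`.
#' @param dir Output directory (created if needed).
#' @param eeg Also synthesize and write EEG EDFs (slow/large),
#'   default FALSE.
#' @param sampling_rate_hz EDF sampling rate when `eeg = TRUE`.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, eeg = FALSE, sampling_rate_hz = 100) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(cohort$records, file.path(dir, "records.csv"))
  files <- purrr::map_dfr(seq_len(nrow(cohort$nights)), function(i) {
    night <- cohort$nights[i, ]
    base <- sprintf("s%02d_%s", night$subject_id, night$condition)
    hyp_file <- file.path(dir, paste0(base, "_hypnogram.csv"))
    write_hypnogram_csv(night$hypnogram[[1]], hyp_file)
    act_file <- file.path(dir, paste0(base, "_counts.csv"))
    readr::write_csv(night$activity[[1]][, c("minute", "counts")], act_file)
    out <- tibble::tibble(file = basename(c(hyp_file, act_file)),
                          subject_id = night$subject_id,
                          condition = night$condition,
                          seed = night$hyp_seed)
    if (eeg) {
      edf_file <- file.path(dir, paste0(base, ".edf"))
      sig <- synthesize_eeg(night$hypnogram[[1]],
                            sampling_rate_hz = sampling_rate_hz,
                            seed = night$hyp_seed)
      write_edf(sig, edf_file, sampling_rate_hz, channel = "Fpz-Cz")
      out <- dplyr::bind_rows(
        out, tibble::tibble(file = basename(edf_file),
                            subject_id = night$subject_id,
                            condition = night$condition,
                            seed = night$hyp_seed))
    }
    out
  })
  readr::write_csv(files, file.path(dir, "manifest.csv"))
  invisible(files)
}
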