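# Independent oracles used across the suite.  Each reimplements the
# quantity under test by brute force or from first principles, sharing
# no code with the package internals it checks.

# Exhaustive most-likely-path search over all 4^n stage sequences.
enumerate_viterbi <- function(X, params) {
  n <- nrow(X)
  logB <- sapply(1:4, function(j) {
    rowSums(dnorm(X, matrix(params$mu[j, ], n, 4, byrow = TRUE),
                  matrix(params$sigma[j, ], n, 4, byrow = TRUE),
                  log = TRUE))
  })
  logB <- matrix(logB, nrow = n)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  score <- log(params$pi)[paths[, 1]] + logB[cbind(1L, paths[, 1])]
  if (n > 1) {
    lQ <- log(params$Q)
    for (t in 2:n) {
      score <- score + lQ[cbind(paths[, t - 1], paths[, t])] +
        logB[cbind(t, paths[, t])]
    }
  }
  paths[which.max(score), ]
}

# random valid HMM parameter draw
random_hmm_params <- function() {
  rdirich <- function() {
    g <- rgamma(4, shape = 1)
    g / sum(g)
  }
  somnr::hmm_params(
    pi = rdirich(),
    Q = t(replicate(4, rdirich())),
    mu = matrix(runif(16, -1, 1), 4, 4),
    sigma = matrix(runif(16, 0.2, 1.5), 4, 4)
  )
}

# Full 2^n sign-flip enumeration of the signed-rank two-sided p-value.
enumerate_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                 mean(w_all >= w_obs - 1e-9)))
}

# Periodogram band-integration estimate of relative band powers.
periodogram_band_powers <- function(epoch, fs, bands = somnr::sleep_bands()) {
  n <- length(epoch)
  P <- Mod(fft(epoch))^2
  fr <- (seq_len(n) - 1) * fs / n
  raw <- vapply(seq_len(nrow(bands)), function(b) {
    sum(P[fr >= bands$low_hz[b] & fr <= bands$high_hz[b] & fr <= fs / 2])
  }, numeric(1))
  raw / sum(raw)
}

# Naive per-epoch counting versions of the sleep indices.
count_rnr <- function(stages, epoch_seconds) {
  rem <- sum(stages == "REM") * epoch_seconds / 60
  nrem <- sum(stages %in% c("Light", "Deep")) * epoch_seconds / 60
  100 * rem / nrem
}
count_ssi <- function(stages, epoch_seconds) {
  shifts <- 0
  for (i in 2:length(stages)) {
    if (stages[i] != stages[i - 1]) shifts <- shifts + 1
  }
  tst_h <- sum(stages != "Wake") * epoch_seconds / 3600
  shifts / tst_h
}
count_sleep_wake <- function(asleep, step_minutes) {
  onset <- NA
  for (i in seq_along(asleep)) {
    if (asleep[i]) { onset <- i; break }
  }
  waso <- 0
  if (!is.na(onset) && onset < length(asleep)) {
    for (i in (onset + 1):length(asleep)) {
      if (!asleep[i]) waso <- waso + step_minutes
    }
  }
  list(se = sum(asleep) / length(asleep),
       tst = sum(asleep) * step_minutes,
       sol = if (is.na(onset)) NA else (onset - 1) * step_minutes,
       waso = if (is.na(onset)) NA else waso)
}

# Direct, windowed re-evaluation of the Sadeh score for one minute.
sadeh_oracle_minute <- function(counts, i) {
  lo <- max(1, i - 5); hi <- min(length(counts), i + 5)
  win <- counts[lo:hi]
  avg <- mean(win)
  nat <- sum(win >= 50 & win < 100)
  prev <- counts[seq(max(1, i - 5), i - 1)]
  if (i == 1) prev <- numeric(0)
  sdv <- if (length(prev) < 2) 0 else sd(prev)
  lg <- log(counts[i] + 1)
  7.601 - 0.065 * avg - 1.08 * nat - 0.056 * sdv - 0.703 * lg
}
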