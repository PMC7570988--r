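#' HMM parameter set for the four-stage sleep model
#'
#' Bundles the three parameter groups of the stager: initial stage
#' probabilities `pi`, the 4x4 row-stochastic transition matrix `Q`,
#' and the Gaussian emission model given by per-stage, per-band means
#' `mu` and standard deviations `sigma` (bands are treated as
#' independent, i.e. diagonal covariance).  Rows and columns follow the
#' fixed stage order Wake, REM, Light, Deep.
#'
#' @param pi Numeric 4-vector of initial probabilities (sums to 1).
#' @param Q 4x4 transition matrix, rows summing to 1, entries >= 0;
#'   `Q[i, j]` is the probability of moving from stage i to stage j at
#'   the next epoch.
#' @param mu 4x4 matrix of emission means (stage x band).
#' @param sigma 4x4 matrix of emission standard deviations; only the
#'   diagonal structure is meaningful (per-stage, per-band sd), all
#'   entries must be positive.
#' @return An object of class `sleep_hmm`.
#' @seealso [hmm_init_params()] for the canonical initialization.
#' @export
hmm_params <- function(pi, Q, mu, sigma) {
  stages <- sleep_stages()
  pi <- as.numeric(pi)
  Q <- as.matrix(Q)
  mu <- as.matrix(mu)
  sigma <- as.matrix(sigma)
  if (length(pi) != 4L || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("`pi` must be a non-negative 4-vector summing to 1", call. = FALSE)
  }
  if (!all(dim(Q) == c(4L, 4L)) || any(Q < 0) ||
      any(abs(rowSums(Q) - 1) > 1e-9)) {
    stop("`Q` must be a 4x4 row-stochastic matrix", call. = FALSE)
  }
  if (!all(dim(mu) == c(4L, 4L)) || !all(dim(sigma) == c(4L, 4L))) {
    stop("`mu` and `sigma` must be 4x4 matrices", call. = FALSE)
  }
  if (any(sigma <= 0)) {
    stop("all emission standard deviations must be positive", call. = FALSE)
  }
  dimnames(Q) <- list(from = stages, to = stages)
  dimnames(mu) <- dimnames(sigma) <- list(stage = stages, band = stages)
  structure(list(pi = stats::setNames(pi, stages), Q = Q,
                 mu = mu, sigma = sigma),
            class = "sleep_hmm")
}

#' Canonical HMM initialization for overnight EEG
#'
#' The stager always starts from the same literature-derived
#' initialization: all initial mass on Wake (a night begins awake), a
#' transition matrix encoding typical overnight stage dynamics (e.g.
#' direct Wake-to-Deep and REM-to-Deep moves start at probability 0),
#' emission means of 0.7 for each stage's own band and 0.1 for the
#' other three, and unit emission standard deviations.
#'
#' @return A [hmm_params()] object.
#' @export
#' @examples
#' p <- hmm_init_params()
#' p$Q["Light", "Deep"]  # 0.16
hmm_init_params <- function() {
  Q0 <- matrix(c(
    0.75, 0.01, 0.24, 0.00,
    0.05, 0.88, 0.07, 0.00,
    0.18, 0.11, 0.55, 0.16,
    0.02, 0.00, 0.14, 0.84
  ), nrow = 4, byrow = TRUE)
  mu0 <- matrix(0.1, 4, 4)
  diag(mu0) <- 0.7
  # the canonical sd "matrix" is the identity, read as unit sd for every
  # band with zero cross-band covariance: stored as per-stage, per-band sds
  hmm_params(pi = c(1, 0, 0, 0), Q = Q0, mu = mu0, sigma = matrix(1, 4, 4))
}

#' @export
print.sleep_hmm <- function(x, ...) {
  cat("<sleep_hmm> 4-state Gaussian-emission HMM\n")
  cat("pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("Q:\n")
  print(round(x$Q, 3))
  invisible(x)
}

# Per-epoch log emission densities: T x 4 matrix of
# log p(x_t | stage = j) under diagonal Gaussians.
log_emissions <- function(X, params) {
  T_ <- nrow(X)
  logB <- matrix(0, T_, 4L)
  for (j in 1:4) {
    mu_j <- matrix(params$mu[j, ], T_, 4L, byrow = TRUE)
    sd_j <- matrix(params$sigma[j, ], T_, 4L, byrow = TRUE)
    logB[, j] <- rowSums(stats::dnorm(X, mu_j, sd_j, log = TRUE))
  }
  logB
}

# Scaled forward pass; returns normalized alpha, scaling constants and
# the per-epoch max log-emission used to keep the scaling finite.
forward_scaled <- function(logB, params) {
  T_ <- nrow(logB)
  m <- apply(logB, 1, max)
  Bs <- exp(logB - m)
  alpha <- matrix(0, T_, 4L)
  cvec <- numeric(T_)
  a <- params$pi * Bs[1, ]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) stop("zero forward probability at epoch 1", call. = FALSE)
  alpha[1, ] <- a / cvec[1]
  for (t in seq_len(T_ - 1L) + 1L) {
    a <- as.vector(alpha[t - 1L, ] %*% params$Q) * Bs[t, ]
    cvec[t] <- sum(a)
    if (cvec[t] <= 0) {
      stop("zero forward probability at epoch ", t, call. = FALSE)
    }
    alpha[t, ] <- a / cvec[t]
  }
  list(alpha = alpha, c = cvec, m = m, Bs = Bs,
       loglik = sum(log(cvec)) + sum(m))
}

backward_scaled <- function(fwd, params) {
  T_ <- nrow(fwd$alpha)
  beta <- matrix(1, T_, 4L)
  for (t in rev(seq_len(T_ - 1L))) {
    beta[t, ] <- as.vector(params$Q %*% (fwd$Bs[t + 1L, ] * beta[t + 1L, ])) /
      fwd$c[t + 1L]
  }
  beta
}

#' Log-likelihood of epoch features under an HMM
#'
#' Marginal log probability of the whole feature sequence, computed
#' with a numerically scaled forward recursion.
#'
#' @param features A [band_powers()] tibble or an n x 4 numeric matrix.
#' @param params A [hmm_params()] object (or a fitted `sleep_hmm_fit`).
#' @return A finite scalar log-likelihood.
#' @export
hmm_loglik <- function(features, params) {
  params <- as_hmm_params(params)
  X <- as_feature_matrix(features)
  if (nrow(X) < 1L) stop("no epochs supplied", call. = FALSE)
  forward_scaled(log_emissions(X, params), params)$loglik
}

as_hmm_params <- function(params) {
  if (inherits(params, "sleep_hmm_fit")) return(params$params)
  if (!inherits(params, "sleep_hmm")) {
    stop("`params` must be a sleep_hmm object (see hmm_params())",
         call. = FALSE)
  }
  params
}

#' Fit the sleep HMM by Baum-Welch expectation-maximization
#'
#' Unsupervised per-recording fit: starting from `params` (by default
#' the canonical initialization, which also anchors the stage
#' identities through the 0.7-diagonal emission means), iterates
#' E-steps (scaled forward-backward) and M-steps updating all three
#' parameter groups until the absolute log-likelihood improvement
#' falls below `tol` or `max_iter` is reached.  The log-likelihood is
#' guaranteed non-decreasing; a decrease beyond numerical tolerance
#' aborts with an internal error.
#'
#' Zero entries of the initial transition matrix are *not* treated as
#' structural zeros: EM may move them away from 0.
#'
#' @param features A [band_powers()] tibble or n x 4 matrix, n >= 2.
#' @param params Starting [hmm_params()]; default [hmm_init_params()].
#' @param max_iter Maximum EM iterations (>= 1), default 100.
#' @param tol Absolute log-likelihood convergence tolerance, default 1e-6.
#' @param update_pi Re-estimate the initial distribution (default TRUE);
#'   set FALSE to hold it at its starting value.
#' @param var_floor Lower bound applied to every emission sd during EM
#'   (default 1e-4) to prevent cluster collapse.
#' @return An object of class `sleep_hmm_fit`: list with elements
#'   `params`, `loglik` (trace, one value per completed iteration,
#'   starting with the initial log-likelihood), `n_iter`, `converged`,
#'   `n_epochs`, `posterior` (n x 4 smoothed stage probabilities).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 4, mean = 0.25, sd = 0.3), ncol = 4)
#' fit <- hmm_fit(X, max_iter = 10)
#' glance(fit)
hmm_fit <- function(features, params = hmm_init_params(), max_iter = 100,
                    tol = 1e-6, update_pi = TRUE, var_floor = 1e-4) {
  params <- as_hmm_params(params)
  X <- as_feature_matrix(features)
  if (nrow(X) < 2L) {
    stop("at least 2 epochs are required to fit the HMM", call. = FALSE)
  }
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  T_ <- nrow(X)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  gamma <- NULL

  for (iter in seq_len(max_iter)) {
    logB <- log_emissions(X, params)
    fwd <- forward_scaled(logB, params)
    beta <- backward_scaled(fwd, params)
    ll <- fwd$loglik
    if (length(ll_trace) == 0L) ll_trace <- ll else ll_trace <- c(ll_trace, ll)
    if (ll < ll_prev - 1e-8 * (1 + abs(ll_prev))) {
      stop("internal error: EM log-likelihood decreased (",
           ll_prev, " -> ", ll, ")", call. = FALSE)
    }
    gamma <- fwd$alpha * beta
    gamma <- gamma / rowSums(gamma)
    # transition posterior, summed over time in one 4xT * Tx4 product
    U <- (fwd$Bs * beta)[2:T_, , drop = FALSE] / fwd$c[2:T_]
    Xi <- params$Q * (t(fwd$alpha[1:(T_ - 1L), , drop = FALSE]) %*% U)

    occ <- colSums(gamma)
    Q_new <- params$Q
    rs <- rowSums(Xi)
    upd <- rs > 1e-12
    Q_new[upd, ] <- Xi[upd, , drop = FALSE] / rs[upd]
    mu_new <- params$mu
    sigma_new <- params$sigma
    for (j in 1:4) {
      if (occ[j] > 1e-10) {
        mu_new[j, ] <- colSums(gamma[, j] * X) / occ[j]
        v <- colSums(gamma[, j] * sweep(X, 2, mu_new[j, ])^2) / occ[j]
        sigma_new[j, ] <- pmax(sqrt(pmax(v, 0)), var_floor)
      }
    }
    pi_new <- if (update_pi) gamma[1, ] else params$pi
    pi_new <- pi_new / sum(pi_new)
    params <- hmm_params(pi_new, Q_new / rowSums(Q_new), mu_new, sigma_new)

    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }

  structure(list(params = params, loglik = ll_trace,
                 n_iter = length(ll_trace), converged = converged,
                 n_epochs = T_, posterior = gamma),
            class = "sleep_hmm_fit")
}

#' @export
print.sleep_hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<sleep_hmm_fit> %d epochs, %d EM iteration(s), logLik %.3f (%s)\n",
    x$n_epochs, x$n_iter, x$loglik[length(x$loglik)],
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Viterbi decoding of epoch features into a hypnogram
#'
#' Returns the jointly most probable stage path under the model, using
#' a log-space dynamic program.  Ties are broken deterministically
#' toward the lower stage index (Wake < REM < Light < Deep).
#'
#' @param features A [band_powers()] tibble or n x 4 matrix.
#' @param params A [hmm_params()] object or fitted `sleep_hmm_fit`.
#' @param epoch_seconds Epoch duration recorded on the output
#'   hypnogram; taken from the features when available.
#' @return A [hypnogram()] of length `nrow(features)`.
#' @export
hmm_decode <- function(features, params, epoch_seconds = NULL) {
  params <- as_hmm_params(params)
  X <- as_feature_matrix(features)
  if (nrow(X) < 1L) stop("no epochs supplied", call. = FALSE)
  if (is.null(epoch_seconds)) {
    epoch_seconds <- attr(features, "epoch_seconds")
  }
  if (is.null(epoch_seconds)) epoch_seconds <- 30
  T_ <- nrow(X)
  logB <- log_emissions(X, params)
  logQ <- log(params$Q)
  delta <- log(params$pi) + logB[1, ]
  psi <- matrix(0L, T_, 4L)
  if (T_ > 1L) {
    for (t in 2:T_) {
      cand <- delta + logQ  # cand[i, j] = delta[i] + log Q[i, j]
      best <- apply(cand, 2, which.max)  # first max -> lower index on ties
      psi[t, ] <- best
      delta <- cand[cbind(best, 1:4)] + logB[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1L) {
    for (t in rev(seq_len(T_ - 1L))) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  hypnogram(sleep_stages()[path], epoch_seconds = epoch_seconds)
}

#' Score an overnight single-channel EEG into a hypnogram
#'
#' The full unsupervised staging pipeline: segment the signal into
#' epochs, extract relative band powers, fit the HMM by EM starting
#' from the canonical initialization, and Viterbi-decode the most
#' probable stage path.  The procedure is deterministic: the same
#' signal always yields the same hypnogram.
#'
#' @param signal Numeric EEG sample vector (a single channel).
#' @param sampling_rate_hz Sampling rate in Hz (>= 100 for the default
#'   bands).
#' @param epoch_seconds Scoring epoch length, default 30 s.
#' @param bands Band definitions, default [sleep_bands()].
#' @param ... Passed on to [hmm_fit()] (e.g. `max_iter`, `tol`,
#'   `update_pi`).
#' @return A [hypnogram()] with the fitted model attached as attribute
#'   `"fit"` and the feature tibble as attribute `"features"`.
#' @export
#' @examples
#' \donttest{
#' hyp <- sample_hypnogram(120, seed = 7)
#' eeg <- synthesize_eeg(hyp, sampling_rate_hz = 100, sd = 0.05, seed = 8)
#' scored <- score_sleep(eeg, 100)
#' mean(scored == hyp)  # label recovery
#' }
score_sleep <- function(signal, sampling_rate_hz, epoch_seconds = 30,
                        bands = sleep_bands(), ...) {
  epochs <- segment_epochs(signal, sampling_rate_hz, epoch_seconds)
  if (nrow(epochs) < 2L) {
    stop("signal must span at least 2 complete epochs", call. = FALSE)
  }
  feats <- band_powers(epochs, sampling_rate_hz, bands = bands)
  fit <- hmm_fit(feats, ...)
  hyp <- hmm_decode(feats, fit, epoch_seconds = epoch_seconds)
  attr(hyp, "fit") <- fit
  attr(hyp, "features") <- feats
  hyp
}
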