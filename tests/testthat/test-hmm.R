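test_that("canonical initialization carries the expected values", {
  p <- hmm_init_params()
  expect_equal(unname(p$pi), c(1, 0, 0, 0))
  expect_equal(unname(p$Q["Light", "Deep"]), 0.16)
  expect_equal(unname(p$Q["Wake", "Deep"]), 0)
  expect_equal(unname(p$Q["REM", "Deep"]), 0)
  expect_true(all(abs(rowSums(p$Q) - 1) < 1e-12))
  expect_equal(unname(diag(p$mu)), rep(0.7, 4))
  expect_equal(unname(p$mu[p$mu != 0.7]), rep(0.1, 12))
  expect_true(all(p$sigma > 0))
})

test_that("parameter validation enforces stochasticity and positive sds", {
  expect_error(hmm_params(c(0.5, 0.5, 0.5, 0.5), diag(4), diag(4),
                          matrix(1, 4, 4)), "summing to 1")
  Qbad <- diag(4); Qbad[1, 1] <- 0.5
  expect_error(hmm_params(c(1, 0, 0, 0), Qbad, diag(4), matrix(1, 4, 4)),
               "row-stochastic")
  expect_error(hmm_params(c(1, 0, 0, 0), diag(4), diag(4), diag(4)),
               "positive")
})

test_that("log-likelihood matches hand-computed Gaussian densities", {
  p <- hmm_init_params()
  x <- c(0.6, 0.2, 0.1, 0.1)
  # one epoch, all initial mass on Wake: just the Wake emission density
  expect_equal(hmm_loglik(matrix(x, 1), p),
               sum(dnorm(x, p$mu[1, ], p$sigma[1, ], log = TRUE)))
  # scaling sigma by 10 changes the density exactly as the formula says
  p10 <- hmm_params(p$pi, p$Q, p$mu, p$sigma * 10)
  expect_equal(hmm_loglik(matrix(x, 1), p10),
               sum(dnorm(x, p$mu[1, ], 10 * p$sigma[1, ], log = TRUE)))
  # degenerate self-loop chain: sum of per-epoch Wake densities
  pid <- hmm_params(c(1, 0, 0, 0), diag(4), p$mu, p$sigma)
  X3 <- rbind(x, x + 0.1, x - 0.2)
  expect_equal(hmm_loglik(X3, pid),
               sum(vapply(1:3, function(t) {
                 sum(dnorm(X3[t, ], p$mu[1, ], p$sigma[1, ], log = TRUE))
               }, numeric(1))))
})

test_that("EM input contracts are enforced", {
  p <- hmm_init_params()
  expect_error(hmm_fit(matrix(0.25, 1, 4)), "at least 2 epochs")
  X <- matrix(rnorm(20), 5, 4)
  expect_error(hmm_fit(X, p, max_iter = 0), "max_iter")
  expect_error(hmm_fit(X, p, tol = 0), "tol")
})

test_that("one EM update is an ascent step and preserves invariants", {
  set.seed(31)
  h <- sample_hypnogram(300, seed = 31)
  X <- simulate_features(h, seed = 32)
  p0 <- hmm_init_params()
  ll0 <- hmm_loglik(X, p0)
  fit1 <- hmm_fit(X, p0, max_iter = 1)
  expect_equal(fit1$n_iter, 1L)
  expect_gte(hmm_loglik(X, fit1$params), ll0)
  # all three parameter groups moved
  expect_false(isTRUE(all.equal(fit1$params$Q, p0$Q)))
  expect_false(isTRUE(all.equal(fit1$params$mu, p0$mu)))
  # pi = (1,0,0,0) is an EM fixed point (the first state is known), so the
  # pi update is visible only from a diffuse start
  pdiff <- hmm_params(rep(0.25, 4), p0$Q, p0$mu, p0$sigma)
  fitd <- hmm_fit(X, pdiff, max_iter = 1)
  expect_false(isTRUE(all.equal(unname(fitd$params$pi), rep(0.25, 4))))
})

test_that("EM trace is monotone and parameters stay valid per iteration", {
  set.seed(77)
  h <- sample_hypnogram(400, seed = 77)
  X <- simulate_features(h, seed = 78)
  # step one iteration at a time so every intermediate state is inspected
  p <- hmm_init_params()
  lls <- numeric(0)
  for (k in 1:12) {
    fit <- hmm_fit(X, p, max_iter = 1)
    p <- fit$params
    lls <- c(lls, fit$loglik)
    expect_true(all(abs(rowSums(p$Q) - 1) < 1e-9))
    expect_true(all(p$Q >= 0))
    expect_lt(abs(sum(p$pi) - 1), 1e-9)
    expect_true(all(p$sigma >= 1e-4))
  }
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("structural zeros of the initial transitions are not clamped", {
  set.seed(5)
  h <- sample_hypnogram(600, seed = 5)
  X <- simulate_features(h, seed = 6)
  fit <- hmm_fit(X, max_iter = 20)
  # q(W,D) starts at 0 but EM is free to move it
  expect_gte(fit$params$Q["Wake", "Deep"], 0)
  expect_true(is.finite(fit$params$Q["Wake", "Deep"]))
})

test_that("pi can be held fixed at the initial distribution", {
  set.seed(9)
  h <- sample_hypnogram(200, seed = 9)
  X <- simulate_features(h, seed = 10)
  fit <- hmm_fit(X, max_iter = 5, update_pi = FALSE)
  expect_equal(unname(fit$params$pi), c(1, 0, 0, 0))
})

test_that("EM recovers parameters in a well-separated emission regime", {
  p0 <- hmm_init_params()
  psep <- hmm_params(p0$pi, p0$Q, p0$mu, matrix(0.15, 4, 4))
  for (s in 1:2) {
    h <- sample_hypnogram(2000, seed = s)
    X <- simulate_features(h, psep, seed = s + 500)
    fit <- hmm_fit(X, psep)
    expect_lt(max(abs(fit$params$mu - p0$mu)), 0.06)
    expect_lt(max(abs(fit$params$Q - p0$Q)), 0.08)
  }
})

test_that("in the unit-sd world EM reaches at least the generator's fit", {
  # with unit emission sds the components overlap heavily; the MLE is not
  # the generator, but its likelihood must dominate the generator's
  h <- sample_hypnogram(2000, seed = 1)
  X <- simulate_features(h, seed = 101)
  fit <- hmm_fit(X)
  expect_gte(hmm_loglik(X, fit$params), hmm_loglik(X, hmm_init_params()))
})

test_that("deterministic alternation between two clusters kills self-loops", {
  set.seed(12)
  n <- 200
  p0 <- hmm_init_params()
  stages <- rep(c("Wake", "Deep"), n / 2)
  X <- p0$mu[match(stages, sleep_stages()), ] +
    matrix(rnorm(n * 4, sd = 0.02), n, 4)
  fit <- hmm_fit(X)
  expect_lt(fit$params$Q["Wake", "Wake"], 0.05)
  expect_lt(fit$params$Q["Deep", "Deep"], 0.05)
})

test_that("Viterbi respects the initial distribution and matches enumeration", {
  p0 <- hmm_init_params()
  # single epoch: pi0 forces Wake whatever the emission says
  expect_equal(as.character(hmm_decode(matrix(c(0.1, 0.1, 0.1, 0.7), 1), p0)),
               "Wake")
  set.seed(20)
  for (s in 1:5) {
    n <- sample(2:8, 1)
    p <- random_hmm_params()
    X <- matrix(rnorm(n * 4), n, 4)
    dec <- as.integer(unclass(hmm_decode(X, p)))
    expect_equal(dec, unname(enumerate_viterbi(X, p)))
  }
})

test_that("forbidden direct Wake-to-Deep transitions route through Light", {
  p0 <- hmm_init_params()
  p <- hmm_params(p0$pi, p0$Q, p0$mu, matrix(0.05, 4, 4))
  stages <- c("Wake", "Wake", "Wake", rep("Deep", 5))
  X <- p0$mu[match(stages, sleep_stages()), ]
  dec <- as.character(hmm_decode(X, p))
  expect_equal(dec[1], "Wake")
  expect_true("Deep" %in% dec)
  first_deep <- which(dec == "Deep")[1]
  expect_equal(dec[first_deep - 1], "Light")  # q(W,D)=0 forbids W->D
  expect_equal(as.integer(unclass(hmm_decode(X, p))),
               unname(enumerate_viterbi(X, p)))
})

test_that("the staging pipeline is deterministic and stage-selective", {
  p0 <- hmm_init_params()
  fs <- 100
  # 10 min Deep-dominant EEG appended to 10 min Wake-dominant EEG
  # (Wake first: the stager assumes recordings begin awake)
  h <- hypnogram(rep(c("Wake", "Deep"), each = 20))
  eeg <- synthesize_eeg(h, fs, sd = 0.05, seed = 99)
  hyp1 <- score_sleep(eeg, fs)
  expect_equal(length(hyp1), 40L)
  expect_gte(mean(as.character(hyp1)[1:20] == "Wake"), 0.8)
  expect_gte(mean(as.character(hyp1)[21:40] == "Deep"), 0.8)
  hyp2 <- score_sleep(eeg, fs)
  expect_identical(as.character(hyp1), as.character(hyp2))
  # fewer than 2 complete epochs cannot be staged
  expect_error(score_sleep(rnorm(59 * fs), fs), "2 complete epochs")
})
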