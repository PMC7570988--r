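test_that("hypnogram sampling follows the chain and the seed contract", {
  # absorbing Wake chain
  h <- sample_hypnogram(50, pi = c(1, 0, 0, 0), Q = diag(4), seed = 1)
  expect_true(all(as.character(h) == "Wake"))
  # determinism
  expect_identical(as.character(sample_hypnogram(200, seed = 9)),
                   as.character(sample_hypnogram(200, seed = 9)))
  expect_error(sample_hypnogram(100), "`seed` is required")
  expect_error(sample_hypnogram(1, seed = 1), "n_epochs")
})

test_that("empirical transition frequencies converge to the chain", {
  Q0 <- hmm_init_params()$Q
  counts <- matrix(0, 4, 4)
  for (s in 1:20) {
    st <- as.integer(unclass(sample_hypnogram(840, seed = 2000 + s)))
    for (t in 2:length(st)) {
      counts[st[t - 1], st[t]] <- counts[st[t - 1], st[t]] + 1
    }
  }
  emp <- counts / rowSums(counts)
  expect_lt(max(abs(emp - Q0)), 0.06)
})

test_that("feature simulation is the emission model, reproducibly", {
  h <- sample_hypnogram(300, seed = 4)
  X1 <- simulate_features(h, seed = 5)
  X2 <- simulate_features(h, seed = 5)
  expect_identical(X1, X2)
  expect_equal(dim(X1), c(300L, 4L))
  # with a tiny sd the features sit on the stage means
  p0 <- hmm_init_params()
  ptight <- hmm_params(p0$pi, p0$Q, p0$mu, matrix(1e-3, 4, 4))
  Xt <- simulate_features(h, ptight, seed = 6)
  expect_lt(max(abs(Xt - p0$mu[as.integer(unclass(h)), ])), 0.01)
})

test_that("synthetic EEG carries the stage band-power structure", {
  p0 <- hmm_init_params()
  deep <- hypnogram(rep("Deep", 100))
  eeg <- synthesize_eeg(deep, 100, seed = 7)
  feats <- band_powers(segment_epochs(eeg, 100), 100)
  m <- mean(feats$p_deep)
  expect_gt(m, 0.6)
  expect_lt(m, 0.8)
  expect_equal(length(eeg), 100 * 30 * 100)
  # deterministic powers when sd = 0: loop-back within filter leakage
  h <- sample_hypnogram(40, seed = 8)
  eeg0 <- synthesize_eeg(h, 100, sd = 0, seed = 9)
  X <- as.matrix(band_powers(segment_epochs(eeg0, 100), 100)[, -1])
  expect_lt(max(abs(X - p0$mu[as.integer(unclass(h)), ])), 0.05)
})

test_that("full-pipeline staging recovers well-separated synthetic nights", {
  h <- sample_hypnogram(240, seed = 10)
  eeg <- synthesize_eeg(h, 100, sd = 0.15, seed = 11)  # 4-sd separation
  scored <- score_sleep(eeg, 100)
  expect_gte(mean(as.character(scored) == as.character(h)), 0.9)
})

test_that("synthetic actigraphy chains into Sadeh scoring", {
  sleepy <- hypnogram(rep(c("Light", "Deep"), 60))
  act <- synthesize_actigraphy(sleepy, wake_rate = 1000, sleep_rate = 0,
                               seed = 12)
  expect_equal(nrow(act), 60)  # length contract: whole minutes
  expect_true(all(act$counts == 0))
  expect_true(all(sadeh_scores(act$counts)$asleep))
  awake <- hypnogram(rep("Wake", 120))
  act2 <- synthesize_actigraphy(awake, wake_rate = 1000, sleep_rate = 0,
                                seed = 13)
  expect_gte(mean(!sadeh_scores(act2$counts)$asleep), 0.95)
  expect_error(synthesize_actigraphy(sleepy, wake_rate = 1, sleep_rate = 2,
                                     seed = 1), "wake_rate > sleep_rate")
})

test_that("injected REM boosts are recovered in ground truth", {
  boosts <- vapply(1:6, function(s) {
    coh <- generate_cohort(n_subjects = 10, conditions = c("A", "SH"),
                           rem_boost_min = c(A = 0, SH = 20),
                           deep_shift_min = c(A = 0, SH = 0),
                           seed = 3000 + s)
    rec <- coh$records
    mean(rec$rem_min[rec$condition == "SH"]) -
      mean(rec$rem_min[rec$condition == "A"])
  }, numeric(1))
  # mean difference equals the injected 20 min up to chain sampling error
  se <- sd(boosts) / sqrt(length(boosts))
  expect_lt(abs(mean(boosts) - 20), max(3 * se, 3))
})

test_that("cohorts are deterministic and structurally complete", {
  nulls <- c(A = 0, SH = 0)  # short test nights: no injected effects
  c1 <- generate_cohort(n_subjects = 4, conditions = c("A", "SH"),
                        rem_boost_min = nulls, deep_shift_min = nulls,
                        n_epochs = 120, seed = 77)
  c2 <- generate_cohort(n_subjects = 4, conditions = c("A", "SH"),
                        rem_boost_min = nulls, deep_shift_min = nulls,
                        n_epochs = 120, seed = 77)
  expect_identical(c1$records, c2$records)
  expect_equal(nrow(c1$nights), 8)
  expect_true(all(c("se", "tst_min", "sol_min", "waso_min", "rem_min",
                    "deep_min", "rnr", "ssi", "act_se", "psqi",
                    "subjective_depth") %in% names(c1$records)))
  expect_true(all(c1$records$subjective_depth %in% 1:7))
  # default PSQI split: half poor, half good
  c3 <- generate_cohort(n_subjects = 10, conditions = "A", n_epochs = 120,
                        seed = 78)
  expect_equal(sum(c3$subjects$sleeper == "poor"), 5)
})

test_that("stage-run conversion shifts exactly the requested minutes", {
  h <- hypnogram(rep(c("Wake", "Light", "Deep", "Light"), c(10, 40, 10, 40)))
  before <- stage_minutes(h)
  shifted <- somnr:::shift_stage_minutes(h, "Light", "REM", 10)
  after <- stage_minutes(shifted)
  expect_equal(after[["REM"]] - before[["REM"]], 10)
  expect_equal(before[["Light"]] - after[["Light"]], 10)
  expect_equal(after[["Wake"]], before[["Wake"]])
  # asking for more than is available warns and converts what exists
  expect_warning(all_gone <- somnr:::shift_stage_minutes(h, "Deep", "REM", 99),
                 "could be converted")
  expect_equal(stage_minutes(all_gone)[["Deep"]], 0)
})
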