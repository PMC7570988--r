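test_that("exact Wilcoxon handles the canonical small-sample cases", {
  expect_error(wilcoxon_exact(1:6, 1:6), "degenerate")
  # constant positive shift, n = 6: statistic 0, p = 2 / 2^6
  res <- wilcoxon_exact(c(5, 7, 8, 9, 11, 13), c(4, 6, 7, 8, 10, 12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.03125)
  expect_error(wilcoxon_exact(1:3, c(2, 3, 4)), "fewer than 5")
  expect_error(wilcoxon_exact(1:4, 1:5), "equal length")
})

test_that("exact p equals 2^n sign-flip enumeration, ties included", {
  set.seed(55)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    expect_equal(wilcoxon_exact(a, b)$p_value, enumerate_wilcoxon_p(a, b))
  }
  # tied absolute differences: integer data
  for (i in 1:5) {
    a <- sample(1:5, 8, replace = TRUE)
    b <- sample(1:5, 8, replace = TRUE)
    d <- a - b
    if (sum(d != 0) < 5) next
    expect_equal(wilcoxon_exact(a, b)$p_value, enumerate_wilcoxon_p(a, b))
  }
})

test_that("exact p matches stats::wilcox.test on tie-free data", {
  set.seed(56)
  for (i in 1:5) {
    a <- rnorm(10)
    b <- rnorm(10)
    ours <- wilcoxon_exact(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value))
    expect_equal(ours$w_plus, unname(ref$statistic))
  }
})

test_that("Spearman correlation behaves like rank-then-Pearson", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  set.seed(57)
  for (i in 1:10) {
    x <- sample(1:4, 12, replace = TRUE)  # heavy ties
    y <- sample(1:4, 12, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    oracle <- stats::cor(rank(x), rank(y))
    expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(58)
  x <- rnorm(20)
  y <- rnorm(20)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base)
  expect_equal(spearman_rho(x, 3 * y + 2), base)
  expect_equal(spearman_rho(x, -y), -base)
})

test_that("PSQI split partitions the cohort at the cutoff", {
  subj <- tibble::tibble(subject_id = 1:10,
                         psqi = c(2, 3, 4, 5, 5, 6, 7, 8, 9, 10))
  sp <- split_by_psqi(subj)
  expect_equal(nrow(sp$poor), 5)
  expect_equal(nrow(sp$good), 5)
  expect_true(all(sp$poor$psqi > 5))
  expect_equal(nrow(split_by_psqi(subj, cutoff = 21)$poor), 0)
  expect_equal(nrow(split_by_psqi(subj, cutoff = 0)$good), 0)
  expect_equal(nrow(sp$poor) + nrow(sp$good), 10)
})

test_that("condition comparison detects an injected REM effect", {
  # the Q0 chain gives night-to-night REM sd ~24 min, so a 40-min boost
  # is the effect size n = 10 paired nights can reliably flag (a 20-min
  # boost sits at ~44% power in this world); the comparison must both
  # detect the injected effect and stay quiet under the null
  run <- function(boost, seeds) {
    vapply(seeds, function(s) {
      coh <- generate_cohort(n_subjects = 10, conditions = c("A", "SH"),
                             rem_boost_min = c(A = 0, SH = boost),
                             deep_shift_min = c(A = 0, SH = 0),
                             n_epochs = 840, seed = 1000 + s)
      condition_comparison(coh$records, indices = "rem_min")$p_value
    }, numeric(1))
  }
  p_boost <- run(40, 1:15)
  p_null <- run(0, 1:15)
  expect_lt(median(p_boost), 0.05)
  expect_lt(median(p_boost), median(p_null))
})

test_that("a null cohort renders a table with missing p-values", {
  rec <- tidyr::expand_grid(subject_id = 1:6, condition = c("A", "S", "SH"))
  rec$rem_min <- 90  # identical across conditions: degenerate comparison
  tab <- condition_comparison(rec, indices = "rem_min")
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$p_value))
  expect_equal(tab$signif, "")
  expect_true(all(c("mean_A", "sd_A", "mean_SH") %in% names(tab)))
})

test_that("unpaired subjects are excluded with a warning", {
  rec <- tidyr::expand_grid(subject_id = 1:8, condition = c("A", "SH"))
  set.seed(60)
  rec$rem_min <- rnorm(nrow(rec), 90, 10)
  rec <- rec[-1, ]  # subject 1 lacks the A night
  expect_warning(tab <- condition_comparison(rec, indices = "rem_min"),
                 "unpaired")
  expect_equal(nrow(tab), 1)
})

test_that("the comparison condition is chosen per index by highest mean", {
  rec <- tidyr::expand_grid(subject_id = 1:6, condition = c("A", "S", "SH"))
  set.seed(61)
  rec$rem_min <- rnorm(nrow(rec), ifelse(rec$condition == "S", 120, 90), 5)
  rec$deep_min <- rnorm(nrow(rec), ifelse(rec$condition == "SH", 110, 80), 5)
  tab <- condition_comparison(rec)
  expect_equal(tab$compared[tab$index == "rem_min"], "S")
  expect_equal(tab$compared[tab$index == "deep_min"], "SH")
  # and a fixed comparison condition overrides the selection
  tab2 <- condition_comparison(rec, compare = "SH")
  expect_true(all(tab2$compared == "SH"))
})
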