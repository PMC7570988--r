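---
title: "Unsupervised sleep staging and sleep-quality indices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised sleep staging and sleep-quality indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnr)
```

## The staging model

`score_sleep()` stages an overnight single-channel EEG without any
training data. The signal is cut into 30-s epochs
(`segment_epochs()`; a trailing partial epoch is dropped), and each
epoch is reduced to the relative power in four stage-associated
frequency bands (`band_powers()`): Wake 35–50 Hz, REM 20–30 Hz, Light
10.15–15.75 Hz, Deep 1–3 Hz. Rows are normalized to sum to one, so an
epoch dominated by delta activity looks like (0.05, 0.05, 0.1, 0.8)
and sits near the "Deep" corner of the simplex.

These feature vectors are modelled by a four-state hidden Markov model
in the fixed stage order Wake, REM, Light, Deep:

* initial distribution $\pi_0 = (1, 0, 0, 0)$ — a recording starts
  with the subject awake;
* transition matrix $Q_0$ with rows (0.75, 0.01, 0.24, 0),
  (0.05, 0.88, 0.07, 0), (0.18, 0.11, 0.55, 0.16),
  (0.02, 0, 0.14, 0.84) — literature-derived overnight dynamics in
  which Deep sleep is entered and left through Light sleep;
* Gaussian emissions with mean 0.7 on each stage's own band and 0.1 on
  the other three, per-band standard deviation 1, and *diagonal*
  covariance. The canonical sd "matrix" is the identity; we read its
  zero off-diagonals as zero cross-band covariance (independent
  bands), not as zero standard deviations, which would be degenerate —
  internally the sd array is therefore all ones.

All three parameter groups are then re-estimated on the recording by
Baum–Welch EM and the hypnogram is the Viterbi path. Two modelling
consequences deserve emphasis:

1. **Stage identity is anchored only by the emission means.** Nothing
   else ties state 4 to "Deep"; if a recording's actual band structure
   contradicts the 0.7-diagonal prior badly enough, EM can relabel
   clusters. In particular $\pi_0 = (1,0,0,0)$ is an exact fixed point
   of the EM update (the first state is *known* to be Wake), so a
   recording that begins with non-Wake content forces a label conflict
   at epoch 1. Recordings should begin with the subject awake, as they
   do in practice.
2. **The zero entries of $Q_0$ are not structural.** EM may move
   q(Wake, Deep) or q(REM, Deep) away from zero; we do not clamp them
   because nothing in the model's provenance declares them impossible,
   only initially improbable. Viterbi under the *initial* matrix still
   respects them exactly (a decoded path reaches Deep through Light).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `epoch_seconds` | 30 | s | the universal sleep-scoring epoch |
| band edges | table above | Hz | fixed stage-band associations; used verbatim, including the oddly specific Light band |
| `n_cycles` (Morlet width) | 7 | cycles | standard trade-off: ~1 Hz spectral sd at 7 Hz; narrow enough to separate the Light and REM bands, wide enough for stable 30-s estimates |
| `max_iter` | 100 | iterations | EM cap; convergence is typically < 20 iterations on real-scale nights |
| `tol` | 1e-6 | log-likelihood units | absolute improvement threshold |
| `var_floor` | 1e-4 | sd units | prevents emission collapse onto replicated feature values |
| `update_pi` | TRUE | — | all three parameter groups are updated; set FALSE to hold π at its start value (both modes are legitimate; re-estimation is the default because the update is part of the standard M-step) |
| RNR denominator | non-REM *sleep* | — | `rnr(include_wake = TRUE)` switches to the literal every-non-REM-epoch reading |
| SSI shifts | all label changes | — | `ssi(count_wake_shifts = FALSE)` counts only shifts within sleep |
| Sadeh constants | 7.601, −0.065, −1.08, −0.056, −0.703 | — | isolated in `sadeh_constants()`; NAT band [50, 100) counts; SD term over the 5 preceding minutes, windows clamped at record edges |
| sleep onset | first sleep-scored step | — | no N-consecutive-epoch smoothing |

Index conventions: durations in minutes, SSI in shifts per hour of
total sleep time (TST = non-Wake time), SE as a fraction in [0, 1].
Undefined ratios (RNR with no non-REM sleep, SOL/WASO with no sleep at
all, precision with no positive calls) are reported as `NA`, never as
0 — a zero would silently deflate cohort averages. The low-level
verbs (`rnr()`, `ssi()`, `sleep_wake_indices()`) raise errors instead,
so a script cannot overlook a degenerate record; the cohort-level
wrapper `sleep_indices()` converts those errors to `NA`.

## The synthetic generator: what it does and does not emulate

`sample_hypnogram()` draws stage sequences from the $(\pi_0, Q_0)$
chain; `synthesize_eeg()` renders each epoch as a sum of four
band-limited Gaussian noise components whose relative powers are drawn
around the stage's emission-mean row (clipped at zero, renormalized,
total variance 1); `synthesize_actigraphy()` draws per-minute Poisson
counts (defaults 150/min awake, 5/min asleep); `generate_cohort()`
assembles subjects × conditions with condition effects injected by
converting stage runs (Light→REM for a REM boost), so the injected
effect is exactly known in minutes.

The generator reproduces the *statistical structure the stager
consumes* — band-power clusters with Markov stage dynamics — and
nothing more. It does not emulate waveform morphology (spindles,
K-complexes, slow-wave shapes), artifacts, mains interference (which
in real data overlaps the 35–50 Hz Wake band), or circadian
architecture (sleep cycles, REM periodicity). The $Q_0$ chain also
shifts stages faster than real hypnograms do (mean run lengths of 2–4
minutes, hence SSI values of 30–50 where real nights sit near 10–15),
and its nights are mutually independent: there is no subject-level
random effect, so paired condition contrasts carry the full
between-night variance. A green end-to-end test therefore establishes
that the algorithmic chain is correct and accurate *when the model's
own assumptions hold*; it says nothing about accuracy on clinical EEG.

The default per-epoch emission scatter is `sd = 0.15`, placing the
0.7-vs-0.1 stage clusters four standard deviations apart. That is the
separation regime the validation suite asserts (≥ 90% staging
accuracy; measured ≈ 99% there). It is a stated world, not a claim
about EEG.

With the *canonical* unit emission sd instead, the four clusters
overlap almost completely (separation 0.6 σ). In that world the
maximum-likelihood parameters at 2000 epochs are not close to the
generator's: EM initialized at the truth drifts to an optimum ~0.2–0.3
away in emission means (an independent HMM implementation converges to
the bit-identical optimum, so this is a property of the likelihood
surface, not of the code). The test suite therefore validates
parameter recovery in the separated regime, and in the unit-sd regime
asserts the property EM actually guarantees: the fitted likelihood
dominates the generator's.

## Numerical choices

* Forward–backward uses per-epoch rescaling with the per-epoch max
  log-emission factored out, so likelihoods of arbitrarily long nights
  stay finite; the log-likelihood is exact, and an EM iteration that
  decreases it beyond 1e-8 relative tolerance aborts as an internal
  error rather than returning silently wrong parameters.
* Viterbi runs in log space; ties break toward the lower stage index
  (Wake < REM < Light < Deep), making decoding deterministic.
* Band filtering is realized in the frequency domain: for each 0.5-Hz
  centre-frequency step across a band, the squared Morlet gain is
  normalized to unit white-noise power on the discrete FFT grid (which
  also compensates truncation at the Nyquist edge of the 35–50 Hz
  band), and centres are averaged and scaled by the band width. This
  makes the estimate directly comparable to integrating a periodogram
  over the band; on white noise the two agree within a few percent
  (asserted at 15%, as the estimators legitimately differ).
* The exact Wilcoxon null distribution is built by dynamic programming
  over the signed-rank generating function on doubled ranks, so tied
  average ranks are integers and the distribution is exact conditional
  on the observed ranks. Zero differences are dropped (the classical
  convention); two-sided p doubles the smaller tail, capped at 1.
  Tests are two-sided throughout; no multiple-testing correction is
  applied by default (`p_adjust = "holm"` is available).
* The comparison condition in `condition_comparison()` is chosen per
  index as the non-baseline condition with the highest group mean
  ("the condition with the highest score"), overridable via `compare`.
* Parameter JSON is written with 17 significant digits, which
  round-trips IEEE doubles bit-exactly. EDF samples are 16-bit
  quantized over each channel's physical range; round trips are exact
  to one quantization step.
* Reference hypnograms arrive as annotation CSVs (onset, duration,
  stage over the classical W/R/1–4/M/? alphabet) and are expanded onto
  the 30-s grid; movement and unscored epochs become `NA` and are
  excluded pairwise during evaluation, never counted as errors.

## Known limitations

* Accuracy on real EEG is not established by this package's tests; the
  optional external benchmark (Sleep-EDFx) is supported through the
  CSV annotation dialect but not bundled.
* Single channel, EEG-only: no EOG/EMG features, so REM detection
  leans entirely on the 20–30 Hz band structure.
* No artifact rejection or notch filtering; 50 Hz mains would leak
  into the Wake band on unfiltered recordings.
* The Sadeh constant block is a published regression for a specific
  device class; counts from other actigraphs may need recalibration.
* At n = 10 subjects the exact Wilcoxon test's attainable two-sided
  levels are discrete (0.049 just below 0.05); power for small
  injected effects is limited accordingly, and the suite sizes its
  detection checks to effects the generator's variance supports.
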