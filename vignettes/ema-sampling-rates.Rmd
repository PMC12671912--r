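---
title: "Choosing EMA sampling rates from the power spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing EMA sampling rates from the power spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(emarate)
```

## The problem

Ecological momentary assessment (EMA) studies prompt participants to rate
symptoms — depressed mood, anhedonia, worry — on Likert or visual-analogue
scales, once to several times a day, for weeks or months. How often should
one prompt? Too rarely and fast symptom dynamics fold back onto slower
apparent rhythms (aliasing); too often and participants drop out.

`emarate` treats the ratings as discrete samples of an underlying
continuous symptom process. The Nyquist–Shannon criterion then says a
sampling rate faster than twice the highest *meaningful* frequency
preserves the signal. The package estimates where that effective band
limit lies:

1. per participant, estimate the power spectral density (PSD) with Welch's
   method (overlapping tapered segments, averaged modified periodograms);
2. summarize each PSD as a **cumulative PSD**: the running sum of non-DC
   power from the slowest to the fastest resolvable frequency, normalized
   to end at 100%;
3. average the per-person curves onto a common grid;
4. locate the curve's **knee** — the frequency beyond which additional
   sampling buys little extra power — with three objective criteria;
5. double the knee frequency and floor its reciprocal to whole days: the
   recommended maximum between-prompt interval.

All frequencies are in cycles/day: 1 means a full cycle per day, 0.1 a
cycle every 10 days. A knee at 0.03 cycles/day (monthly fluctuations)
doubles to 0.06/day, i.e. a prompt at least every 16 days.

```{r pipeline}
spec <- synthetic_spec(
  components = list(c(1/30, 1.2, 0), c(1/14, 0.9, 2), c(1/7, 0.6, 4)),
  baseline = 4, noise_sd = 0.5, n_days = 60, samples_per_day = 1,
  scale_min = 1, scale_max = 7, quantize = TRUE, seed = 42)
cohort <- generate_cohort(spec, 25, between_person_sd = 0.5,
                          random_phase = TRUE, seed = 42)
fit <- ema_spectrum(cohort, params = welch_params(segment_length = 32))
fit
plot(fit)
```

## The model and its assumptions

The synthetic generator — the package's stand-in for raw study data —
draws each rating as

    value = baseline + sum_k a_k sin(2 pi f_k t + phi_k) + e(t)

with white Gaussian noise `e` (optionally plus a 1/f component), then
clips to the declared scale and, for Likert items, rounds to integer
steps (clip before round, so emitted values always sit on the scale).
Sampling schedules are daily or four-times-daily; the 4x/day prompts sit
evenly inside a 09:00–21:00 window by default, mirroring designs that do
not prompt at night (a switch gives uniform 24-h spacing). Missingness
removes prompts independently with a given probability, then repairs the
mask so no run of fully-missing days exceeds the declared bound.

What the generator deliberately does *not* model: autoregressive or
regime-switching mood dynamics, event-contingent sampling, circadian
waveform shape beyond sinusoids. Passing tests on these cohorts therefore
demonstrates that the *estimator* recovers known spectral structure under
EMA-like sampling, scale quantization and missingness — not that real
symptom series are sums of sinusoids. What counts as a "realistic" noise level for symptom ratings is an
open question: amplitudes and noise are deliberately free parameters.

## Preprocessing rules

Participants are retained when their longest *valid run* spans at least
20 days, where runs of up to 3 consecutive fully-missing days are bridged
(both thresholds configurable). Retained series are truncated to that run
(ties keep the earliest), and missing prompts inside the run are filled by
linear interpolation on the scheduled prompt grid — never extrapolated.
For 4x-daily data a day counts as missing only when all of its prompts
are missing; within-day gaps are interpolated on the prompt grid. The
exclusion log (attached to the filtered cohort) records a per-participant
reason, making the rule auditable. Filtering is idempotent, and
interpolation preserves every observed (time, value) pair.

## Spectral estimation choices

* **Segment length.** Default: the largest power of two at most half the
  series length, floored at 16 — at 50% overlap this yields three or more
  averaged segments for typical 30–90-day series. For *short* baselines
  where slow cycles matter, resolution matters more than variance
  reduction: a 60-day window contains only two cycles of a monthly
  component, and the default grid (bin width 1/16 cycles/day) cannot even
  represent a knee near 1/30. The band-limit recovery experiments and
  personalized recommendations therefore use full-length single segments
  (resolution 1/T); the trade-off is noisier per-bin power, which the
  cumulative curve largely integrates away.
* **Window and detrending.** Hann taper, per-segment mean removal. The
  cumulative curve must start near 0%, which requires excluding the
  zero-frequency (DC) bin — the series mean is a level, not a
  fluctuation. The DC bin is therefore dropped from cumulative
  normalization (`include_dc = TRUE` restores it).
* **Scaling.** One-sided density scaling: summing power times bin width
  recovers the variance of the detrended series. This is exact for a
  rectangular single segment (the test suite checks equality with a
  direct-DFT periodogram at 1e-10) and unbiased but noisy under Hann
  tapering — a few percent realization scatter with a handful of
  segments, which is why conservation checks compare the Monte-Carlo mean.
* **Averaging grid.** Participants differ in length, so per-person curves
  are linearly interpolated onto 256 log-spaced frequencies spanning the
  range common to all members before averaging.
* **Irregular prompts.** Four-times-daily daytime prompts are regularized
  to the nominal 0.25-day grid before Welch estimation. Irregular-sampling
  estimators (Lomb–Scargle) are out of scope.

## Knee criteria

Three objective criteria are always computed side by side; none is "the"
knee.

* **Kneedle**: min–max normalize (frequency, cumulative percent), form the
  difference curve `y − x`, take the frequency at its maximum; a maximum
  that does not exceed `sensitivity ×` the mean normalized x-step (as for
  a straight line) is an explicit "no knee". On the linear axis the curve
  is anchored at the origin, where the DC-excluded cumulative spectrum
  conceptually starts — without the anchor, a knee falling in the first
  resolved bin would be normalized away. A log-frequency orientation is
  available by argument.
* **Second derivative**: after light smoothing (3-point moving average),
  the frequency of maximum downward curvature of cumulative percent
  against log-frequency. Needs a resolved point on each side of the bend,
  so it is the least reliable criterion at coarse resolution.
* **Threshold**: the smallest frequency at which the curve reaches a set
  percentage (default 90%). Simple and always defined, but sensitive to
  broadband noise and spectral leakage: on short windows a slow component
  leaks power above the true band edge, delaying the 90% crossing — with
  60-day windows and a monthly band limit the crossing can land beyond
  twice the true edge. This is why the default recommendation uses
  Kneedle, with threshold as the fallback when no knee exists.

The recommendation doubles the knee frequency and floors the reciprocal
interval to whole days (a 0.03 cycles/day knee gives "at least every 16
days"). When the chosen criterion finds no knee (featureless spectra),
the pipeline falls back to the 90% threshold and flags it. A constant
series has no spectral power at all and is rejected with an informative
error rather than a fabricated recommendation.

## Cohort comparisons

Between-cohort differences in spectral heterogeneity are tested per
frequency bin: for each bin inside an analysis band, a Levene test
compares the spread (across participants) of the point-percentage change
of the cumulative PSD — the relative increase from one bin to the next —
between cohorts, with Bonferroni correction over the bins inside the band
only. The classic mean-centered statistic is the default (the
median-centered Brown–Forsythe variant is an argument away).

A calibration caveat, measured rather than assumed: per-bin
point-percentage changes are ratios of positive quantities and are
right-skewed whenever between-person heterogeneity is strong (random
phases, widely spread amplitudes) or periodogram averaging is sparse.
The classic Levene test is anticonservative under such skew — simulations
here put its per-bin size at 0.07–0.09 for 20-member cohorts with one or
two Welch segments, and the statistic also runs slightly hot (≈0.055)
even on normal data with 20 per group. With intensive schedules and
heavy averaging (60 days at 4 uniformly spaced prompts/day, segment
length 16 at 75% overlap — 57 averaged segments), cohorts of 40, and
the tested band restricted to noise-dominated bins clear of the slow
components, the nominal 5% level holds (measured ~0.055 across several
thousand simulated null bins). The package's calibration experiment uses
that design; for sparse-segment settings use `center = "median"`.

The band-power experiment asks whether tripling the between-person
amplitude spread of a 21-day component — a cohort whose members differ
three times more in how strongly they express a three-week symptom cycle,
as a stylized clinical contrast — is flagged inside the 18–26-day band.
This needs a native frequency bin inside the band, hence 120-day daily
windows with segment length 64 at 75% overlap (bin width ≈ 0.0156
cycles/day, four averaged segments); with 35 members per cohort the
band is flagged (Bonferroni-adjusted, 5% level) in roughly 90% of
simulated contrasts.

## Personalized protocol

`personalized_recommendation()` chains the whole pipeline for one person's
high-frequency baseline: inclusion check, truncation, interpolation,
Welch, cumulative curve, knee, doubled rate. `validate_rate()` then
simulates monitoring at a candidate interval: it subsamples the baseline,
reconstructs the trajectory on the native grid by linear interpolation
(what a clinician eyeballing a chart effectively does) and by windowed-
sinc band-limited interpolation, and scores root-mean-square error
against the held-out points, normalized by the scale range. The sinc
kernel is truncated (half-width 16 samples, cosine-squared taper,
weights renormalized to a partition of unity); its edge transient decays
within a few sampling intervals, so the scored region excludes four
intervals at each end by default. Reconstruction from supra-Nyquist
subsampling of a band-limited signal stays within a few percent of the
amplitude; sub-Nyquist subsampling aliases and the error grows — the
package asserts the ordering, not a universal error bound.
`subgroup_recommendations()` aggregates per-person results by stratum
(mean and SD of knee frequency, modal interval).

## Numerical and degenerate-input conventions

* Ties between equal-length valid runs keep the earliest; `which.max`
  determinism also fixes knee ties at the first maximizing bin.
* Segment lengths are rounded down to even so the grid ends exactly at
  the Nyquist frequency; a requested segment longer than the series falls
  back to one full-length segment with a warning.
* Cumulative curves reject all-zero spectra (nothing to normalize).
* Curve correlation of a constant curve is reported as `NA`, not 0.
* All simulation entry points take integer seeds and restore the caller's
  RNG state; per-participant seeds are `seed + i - 1`, keeping cohorts
  reproducible and members independent.

## Problem sizes used in the shipped experiments

Band-limit recovery: 100 replicates per cutoff (monthly, biweekly,
weekly) of 50-participant, 60-day daily cohorts whose generating process
puts at least 90% of its power below the cutoff (checked analytically
from the component amplitudes and noise variance). Levene size: 160
null cohort pairs (40 members each) of 60-day 4x-daily series, over
1,100 per-bin tests. Levene power: 100 contrasts of 35-member, 120-day
daily cohorts. Reconstruction and aliasing checks: single series of 84–384
samples. These sizes keep the full suite within a few minutes on one
core while leaving Monte-Carlo margins well clear of the asserted
thresholds.

## Known limitations

* Welch on a regularized grid ignores within-day prompt-time jitter;
  strongly event-contingent designs need irregular-sampling estimators.
* The second-derivative knee is unreliable when the bend sits in the
  first resolved bin.
* The classic Levene calibration caveat above.
* Slopes, knees and recommendations inherit the resolution of the
  frequency grid: with a 60-day window the interval recommendation is
  quantized by bins of 1/60 cycles/day.
* The synthetic generator's stationary sinusoid-plus-noise model cannot
  probe abrupt state transitions; a sharp change spreads power across all
  frequencies and has no finite band limit.
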