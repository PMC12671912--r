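# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A clean daily sinusoid-on-baseline series (no noise, no quantization).
make_sine_series <- function(f = 1 / 7, amplitude = 2, n_days = 56,
                             baseline = 4, phase = 0, interval = 1,
                             scale_min = 0, scale_max = 8, id = "P1") {
  t <- (seq_len(round(n_days / interval)) - 1) * interval
  ema_series(id, t, baseline + amplitude * sin(2 * pi * f * t + phase),
             scale_min, scale_max, interval = interval)
}

# Direct-DFT one-sided periodogram oracle, written independently of
# welch_psd(): plain rectangular-window periodogram of the mean-removed
# signal, density scaling.
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  nf <- n %/% 2 + 1
  P <- Mod(X[seq_len(nf)])^2 / (fs * n)
  if (nf > 2) P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
  list(freqs = (seq_len(nf) - 1) * fs / n, power = P)
}

# Piecewise-linear cumulative curve rising steeply to `y_at_knee` percent at
# `f_knee`, then slowly to 100 at `f_max`.
make_knee_curve <- function(f_knee = 0.03, y_at_knee = 90, f_max = 0.5,
                            n1 = 30, n2 = 60) {
  f <- c(seq(f_knee / n1, f_knee, length.out = n1),
         seq(f_knee + (f_max - f_knee) / n2, f_max, length.out = n2))
  y <- c(seq(y_at_knee / n1, y_at_knee, length.out = n1),
         seq(y_at_knee + (100 - y_at_knee) / n2, 100, length.out = n2))
  emarate:::new_cumulative(f, y)
}

# Low-pass synthetic cohort: >= 90% of generating-process power below f_c.
# Component amplitudes and noise are chosen so that the analytic power
# budget (sum a_i^2/2 below f_c vs white-noise power above) satisfies the
# 90% condition; VAS-style scale avoids quantization noise.
lowpass_spec <- function(f_c, n_days = 60, noise_sd = 4, seed = 1) {
  synthetic_spec(
    components = list(c(0.30 * f_c, 12, 0), c(0.55 * f_c, 11, 2),
                      c(0.80 * f_c, 10, 4), c(0.95 * f_c, 9, 1)),
    baseline = 50, noise_sd = noise_sd, n_days = n_days,
    samples_per_day = 1, scale_min = 0, scale_max = 100,
    quantize = FALSE, seed = seed)
}

# Fraction of generating-process power below f_c for a spec (white noise
# spreads its variance uniformly up to the Nyquist frequency).
power_fraction_below <- function(spec, f_c) {
  sig <- sum(spec$components$amplitude^2 / 2 *
               (spec$components$frequency <= f_c))
  tot_sig <- sum(spec$components$amplitude^2 / 2)
  f_nyq <- spec$samples_per_day / 2
  noise_below <- spec$noise_sd^2 * min(1, f_c / f_nyq)
  (sig + noise_below) / (tot_sig + spec$noise_sd^2)
}

# Base spec for cohort-comparison simulations: 120-day daily VAS series with
# slow-to-fast components, including one inside the 18-26-day band.
compare_spec <- function(seed, n_days = 120) {
  synthetic_spec(
    components = list(c(1 / 30, 10, 0), c(1 / 21, 8, 2),
                      c(1 / 10, 8, 4), c(1 / 5, 6, 1)),
    baseline = 50, noise_sd = 3, n_days = n_days, samples_per_day = 1,
    scale_min = 0, scale_max = 100, quantize = FALSE, seed = seed)
}

# Intensive 4x-daily variant used for the type-I calibration of the
# frequency-wise variance test: 60 days x 4 uniformly spaced prompts supply
# heavy Welch segment averaging (57 segments at 75% overlap, L = 16), so
# per-bin dispersion across participants is close to symmetric -- the
# regime where the classic mean-centered Levene test holds nominal size.
compare_spec_4x <- function(seed) {
  synthetic_spec(
    components = list(c(1 / 30, 10, 0), c(1 / 21, 8, 2),
                      c(1 / 10, 8, 4), c(1 / 5, 6, 1)),
    baseline = 50, noise_sd = 3, n_days = 60, samples_per_day = 4,
    scale_min = 0, scale_max = 100, quantize = FALSE,
    daytime_window = FALSE, seed = seed)
}

cohort_pct_changes <- function(cohort, params) {
  lapply(cohort$members,
         function(s) pct_change(cumulative_psd(welch_psd(s, params))))
}
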