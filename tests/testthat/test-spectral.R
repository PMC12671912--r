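test_that("single-segment rectangular Welch equals the direct-DFT periodogram", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(c(48, 60, 64), 1)
    x <- stats::rnorm(n, mean = 50, sd = 5)
    s <- ema_series("P", 0:(n - 1), x, 0, 100, interval = 1)
    p <- welch_psd(s, welch_params(segment_length = n - n %% 2,
                                   overlap_fraction = 0,
                                   window = "rectangular", detrend = "mean"))
    orc <- oracle_periodogram(x[seq_len(n - n %% 2)], fs = 1)
    expect_equal(p$freqs, orc$freqs, tolerance = 1e-12)
    nz <- orc$power > 0
    expect_lt(max(abs(p$power[nz] - orc$power[nz]) / orc$power[nz]), 1e-10)
  }
})

test_that("welch grid spans 0 to Nyquist and a constant series has no AC power", {
  s <- make_sine_series(interval = 0.25, n_days = 30)
  p <- welch_psd(s)
  expect_equal(max(p$freqs), 2)           # 4/day sampling -> 2 cycles/day
  expect_equal(min(p$freqs), 0)
  const <- ema_series("P", 0:49, rep(4, 50), 1, 7, interval = 1)
  pc <- welch_psd(const)
  expect_lt(max(pc$power[pc$freqs > 0]), 1e-20)
})

test_that("power integrates to the variance for white noise (Parseval)", {
  # the Welch total is an unbiased but noisy estimate of the variance (a few
  # percent realization scatter with a handful of segments), so the 5% check
  # is on the Monte-Carlo mean and a looser one on each realization
  set.seed(99)
  ratios <- replicate(10, {
    x <- stats::rnorm(1024, mean = 50, sd = 4)
    s <- ema_series("P", 0:1023, x, 0, 100, interval = 1)
    p <- welch_psd(s)
    sum(p$power) * diff(p$freqs[1:2]) / stats::var(x)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.05)
  expect_true(all(abs(ratios - 1) < 0.15))
})

test_that("band-averaged white-noise PSD is flat across quartile bands", {
  # Monte-Carlo over 50 seeds: quartile-band means of the averaged spectrum
  # within 10% of each other
  accum <- NULL
  for (seed in 1:50) {
    set.seed(seed)
    x <- stats::rnorm(2000, 50, 4)
    p <- welch_psd(ema_series("P", 0:1999, x, 0, 100, interval = 1))
    pos <- p$freqs > 0
    accum <- if (is.null(accum)) p$power[pos] else accum + p$power[pos]
  }
  accum <- accum / 50
  q <- cut(seq_along(accum), 4)
  bandmeans <- tapply(accum, q, mean)
  expect_lt((max(bandmeans) - min(bandmeans)) / mean(bandmeans), 0.1)
})

test_that("welch shortens the segment with a warning when the series is short", {
  s <- make_sine_series(n_days = 20)
  expect_warning(p <- welch_psd(s, welch_params(segment_length = 64)),
                 "single full-length segment")
  expect_equal(p$n_segments, 1L)
})

test_that("cumulative curves are normalized, monotone, and shaped by the spectrum", {
  # any valid PSD: ends at 100, nondecreasing
  spec <- lowpass_spec(1 / 14, seed = 4)
  p <- welch_psd(generate_series(spec))
  cum <- cumulative_psd(p)
  expect_equal(utils::tail(cum$cum_percent, 1), 100, tolerance = 1e-9)
  expect_true(all(diff(cum$cum_percent) >= -1e-12))
  # single sinusoid: jump from ~0 to ~100 at the component's bin
  s <- make_sine_series(f = 1 / 8, n_days = 64)
  cums <- cumulative_psd(welch_psd(s))
  below <- max(cums$cum_percent[cums$freqs < 1 / 8 - 0.04])
  above <- min(cums$cum_percent[cums$freqs > 1 / 8 + 0.04])
  expect_lt(below, 5)
  expect_gt(above, 95)
  # equal power per bin: cumulative linear in bin index
  flatp <- structure(list(freqs = seq(0, 0.5, by = 0.05),
                          power = c(3, rep(2, 10)),
                          params = welch_params(), sampling_interval = 1,
                          n_segments = 1), class = "psd_estimate")
  cumf <- cumulative_psd(flatp)
  expect_equal(cumf$cum_percent, seq(10, 100, by = 10), tolerance = 1e-12)
  # all-zero power is rejected
  zerop <- structure(list(freqs = seq(0, 0.5, 0.1), power = rep(0, 6),
                          params = welch_params(), sampling_interval = 1,
                          n_segments = 1), class = "psd_estimate")
  expect_error(cumulative_psd(zerop), "zero")
})

test_that("averaging cumulative curves is a pointwise mean on a shared grid", {
  spec <- lowpass_spec(1 / 10, seed = 6)
  coh <- generate_cohort(spec, 8, between_person_sd = 3, random_phase = TRUE,
                         seed = 6)
  curves <- lapply(coh$members, function(s) cumulative_psd(welch_psd(s)))
  # identical curves average to themselves
  same <- average_cumulative(list(curves[[1]], curves[[1]]))
  direct <- resample_cumulative(curves[[1]], same$freqs)
  expect_equal(same$cum_percent, direct$cum_percent, tolerance = 1e-12)
  # mean lies between pointwise min and max
  avg <- average_cumulative(curves)
  mat <- vapply(curves, function(cv)
    resample_cumulative(cv, avg$freqs)$cum_percent,
    numeric(length(avg$freqs)))
  expect_true(all(avg$cum_percent >= apply(mat, 1, min) - 1e-9))
  expect_true(all(avg$cum_percent <= apply(mat, 1, max) + 1e-9))
  # permutation invariance
  shuffled <- average_cumulative(curves[sample(length(curves))])
  expect_equal(avg$cum_percent, shuffled$cum_percent, tolerance = 1e-12)
  expect_error(average_cumulative(list()), "at least one")
})

test_that("point-percentage changes follow the ratio definition", {
  cum <- emarate:::new_cumulative(c(0.1, 0.2), c(50, 75))
  expect_equal(pct_change(cum)$pct_change, 50)
  flat <- emarate:::new_cumulative(seq(0.1, 0.5, 0.1), c(40, 60, 60, 60, 100))
  pc <- pct_change(flat)
  expect_equal(pc$pct_change[2:3], c(0, 0))
})

test_that("an added 2-day cycle produces a pct-change peak at 1/2 cycles/day", {
  base <- list(c(1 / 30, 2, 0), c(1 / 14, 1.5, 1))
  with_fast <- c(base, list(c(0.48, 1.2, 2)))
  mk <- function(cmps, seed) {
    spec <- synthetic_spec(components = cmps, baseline = 50, noise_sd = 1,
                           n_days = 120, scale_min = 0, scale_max = 100,
                           quantize = FALSE, seed = seed)
    coh <- generate_cohort(spec, 10, between_person_sd = 3,
                           random_phase = TRUE, seed = seed)
    avg <- average_cumulative(lapply(coh$members, function(s)
      cumulative_psd(welch_psd(s, welch_params(segment_length = 64)))))
    pct_change(avg)
  }
  pc <- mk(with_fast, 17)
  upper <- pc$freqs > 0.3
  peak_f <- pc$freqs[upper][which.max(pc$pct_change[upper])]
  expect_lt(abs(peak_f - 0.48), 0.06)
  # without the fast component the same region shows no comparable peak
  pc0 <- mk(base, 17)
  expect_gt(max(pc$pct_change[upper]),
            3 * max(pc0$pct_change[pc0$freqs > 0.3]))
})

test_that("log-log slope recovers exact power laws", {
  f <- seq(0.01, 0.5, length.out = 200)
  half <- emarate:::new_cumulative(f, 100 * sqrt(f / 0.5))
  expect_equal(loglog_slope(half, f_min = 1 / 30), 0.5, tolerance = 1e-6)
  const <- emarate:::new_cumulative(f, rep(80, 200))
  expect_equal(loglog_slope(const, f_min = 1 / 30), 0, tolerance = 1e-9)
  tiny <- emarate:::new_cumulative(f[1:3], c(10, 20, 100))
  expect_error(loglog_slope(tiny, f_min = 0.4), ">= 3 points")
})

test_that("alias_frequency folds into [0, f_s/2] and matches empirical spectra", {
  expect_equal(alias_frequency(0.4, 1), 0.4)
  expect_equal(alias_frequency(1, 1), 0)
  expect_equal(alias_frequency(0.6, 1), 0.4)
  # folding closure + empirical check over 20 random (f_true, interval) pairs
  set.seed(77)
  for (i in 1:20) {
    f_true <- stats::runif(1, 0.05, 0.45)
    k <- sample(2:4, 1)                      # downsampling factor
    fs_new <- 1 / k
    predicted <- alias_frequency(f_true, fs_new)
    expect_gte(predicted, 0)
    expect_lte(predicted, fs_new / 2 + 1e-12)
    s <- make_sine_series(f = f_true, n_days = 24 * k * 4,
                          phase = stats::runif(1, 0, 2 * pi))
    ds <- downsample_series(s, k)
    p <- welch_psd(ds, welch_params(segment_length = 32))
    pos <- p$freqs > 0
    df <- diff(p$freqs[1:2])
    empirical <- p$freqs[pos][which.max(p$power[pos])]
    expect_lt(abs(empirical - predicted), df + 1e-12)
  }
})

test_that("downsampling keeps nearest-grid samples", {
  s <- make_sine_series(n_days = 30)
  expect_equal(downsample_series(s, 1)$times, s$times)
  half <- downsample_series(s, 2)
  expect_true(abs(length(half$times) - 15) <= 1)
  expect_error(downsample_series(s, 0.5), "native")
})

test_that("nyquist_limit doubles the interval into the minimum resolvable period", {
  daily <- nyquist_limit(1)
  expect_equal(daily$f_nyquist, 0.5)
  expect_equal(daily$min_resolvable_period, 2)
  four <- nyquist_limit(0.25)
  expect_equal(four$min_resolvable_period, 0.5)
  weekly <- nyquist_limit(7)
  expect_equal(weekly$f_nyquist, 1 / 14)
  expect_error(nyquist_limit(0), "sampling_interval_days")
})
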