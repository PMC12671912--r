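#' Welch estimation parameters
#'
#' @param segment_length Samples per segment; `NULL` selects the largest
#'   power of two at most half the series length, floored at 16. Odd values
#'   are rounded down to even so the grid reaches the Nyquist frequency
#'   exactly.
#' @param overlap_fraction Fractional overlap between consecutive segments
#'   (default 0.5, the standard choice).
#' @param window Taper: `"hann"` or `"rectangular"`.
#' @param detrend Per-segment detrending: `"mean"` (remove the segment mean)
#'   or `"none"`.
#' @return Object of class `welch_params`.
#' @export
welch_params <- function(segment_length = NULL, overlap_fraction = 0.5,
                         window = c("hann", "rectangular"),
                         detrend = c("mean", "none")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  if (!is.finite(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_field("overlap_fraction", "must satisfy 0 <= overlap_fraction < 1")
  }
  if (!is.null(segment_length)) {
    if (!is_count(segment_length) || segment_length < 4) {
      stop_field("segment_length", "must be an integer >= 4")
    }
    segment_length <- as.integer(segment_length)
  }
  structure(list(segment_length = segment_length,
                 overlap_fraction = overlap_fraction,
                 window = window, detrend = detrend),
            class = "welch_params")
}

default_segment_length <- function(n) {
  max(16L, 2L^floor(log2(max(n, 2) / 2)))
}

taper_window <- function(name, L) {
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1)),
         rectangular = rep(1, L))
}

#' Welch power spectral density of an EMA series
#'
#' Splits the (uniformly sampled, post-interpolation) series into overlapping
#' tapered segments, computes a modified periodogram for each, and averages.
#' Power is one-sided and density-scaled: summing `power * delta_f` over the
#' grid recovers the variance of the detrended signal up to the usual
#' window-correction tolerance. Frequencies are in cycles/day; the grid runs
#' from 0 (DC) to the Nyquist frequency `1/(2*interval)`.
#'
#' @param series An [ema_series()] with uniform spacing `series$interval`.
#' @param params A [welch_params()].
#' @return Object of class `psd_estimate` with elements `freqs`, `power`,
#'   `params`, `sampling_interval`, `n_segments`.
#' @export
welch_psd <- function(series, params = welch_params()) {
  stopifnot(inherits(series, "ema_series"), inherits(params, "welch_params"))
  x <- series$values
  n <- length(x)
  if (n < 4) stop("series too short for spectral estimation (need >= 4 samples)",
                  call. = FALSE)
  fs <- 1 / series$interval
  L <- params$segment_length
  if (is.null(L)) L <- default_segment_length(n)
  if (L > n) {
    warning(sprintf("segment_length %d exceeds series length %d; using a single full-length segment",
                    L, n), call. = FALSE)
    L <- n
  }
  L <- L - L %% 2L                      # even length: grid ends at Nyquist
  step <- max(1L, as.integer(floor(L * (1 - params$overlap_fraction))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- taper_window(params$window, L)
  U <- sum(w^2)
  nfreq <- L %/% 2L + 1L
  acc <- numeric(nfreq)
  for (st in starts) {
    seg <- x[st:(st + L - 1L)]
    if (params$detrend == "mean") seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    P <- (Mod(X)^2) / (fs * U)
    P[2:(nfreq - 1L)] <- 2 * P[2:(nfreq - 1L)]   # one-sided, Nyquist unpaired
    acc <- acc + P
  }
  power <- acc / length(starts)
  structure(list(freqs = seq(0, nfreq - 1L) * fs / L,
                 power = power,
                 params = params,
                 sampling_interval = series$interval,
                 n_segments = length(starts),
                 participant_id = series$participant_id,
                 item = series$item),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d frequencies in [0, %.4g] cycles/day, %d segment(s), %s window\n",
              length(x$freqs), max(x$freqs), x$n_segments, x$params$window))
  invisible(x)
}

#' Cumulative PSD as percent of total non-DC power
#'
#' Running sum of power from the lowest positive frequency upward,
#' normalized to end at 100. The zero-frequency (DC) bin, which encodes the
#' series mean rather than any fluctuation, is excluded from the
#' normalization by default.
#'
#' @param psd A [psd_estimate()].
#' @param include_dc Include the DC bin in the running sum (default `FALSE`).
#' @return Object of class `cumulative_psd` with `freqs` and `cum_percent`
#'   (nondecreasing, ending at 100).
#' @export
cumulative_psd <- function(psd, include_dc = FALSE) {
  stopifnot(inherits(psd, "psd_estimate"))
  keep <- if (include_dc) seq_along(psd$freqs) else which(psd$freqs > 0)
  p <- psd$power[keep]
  total <- sum(p)
  if (!is.finite(total) || total <= 0) {
    stop("all spectral power is zero; no normalizable cumulative spectrum",
         call. = FALSE)
  }
  structure(list(freqs = psd$freqs[keep],
                 cum_percent = 100 * cumsum(p) / total,
                 include_dc = include_dc),
            class = "cumulative_psd")
}

#' @export
print.cumulative_psd <- function(x, ...) {
  cat(sprintf("<cumulative_psd> %d points over [%.4g, %.4g] cycles/day\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

new_cumulative <- function(freqs, cum_percent) {
  structure(list(freqs = freqs, cum_percent = cum_percent, include_dc = FALSE),
            class = "cumulative_psd")
}

#' Resample a cumulative PSD curve onto a frequency grid
#'
#' Linear interpolation in linear frequency; values outside the curve's
#' range are clamped to the end values.
#'
#' @param cum A [cumulative_psd()].
#' @param grid Target frequencies, cycles/day, ascending.
#' @return A [cumulative_psd()] on `grid`.
#' @export
resample_cumulative <- function(cum, grid) {
  stopifnot(inherits(cum, "cumulative_psd"))
  y <- stats::approx(cum$freqs, cum$cum_percent, xout = grid, rule = 2)$y
  new_cumulative(grid, y)
}

#' Average cumulative PSD curves across participants
#'
#' Interpolates each per-person curve onto a common grid and takes the
#' pointwise mean, yielding the normative group curve. By default the grid
#' has `n_grid` log-spaced points from the largest per-person minimum
#' positive frequency to the smallest per-person maximum, so that no curve
#' is extrapolated.
#'
#' @param curves List of [cumulative_psd()] objects (>= 1).
#' @param grid Optional explicit frequency grid, cycles/day.
#' @param n_grid Number of log-spaced grid points when `grid` is `NULL`.
#' @return A [cumulative_psd()] on the common grid.
#' @export
average_cumulative <- function(curves, grid = NULL, n_grid = 256L) {
  if (!length(curves)) stop("need at least one cumulative curve", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "cumulative_psd")))
  if (is.null(grid)) {
    lo <- max(vapply(curves, function(cv) min(cv$freqs[cv$freqs > 0]), numeric(1)))
    hi <- min(vapply(curves, function(cv) max(cv$freqs), numeric(1)))
    if (!(lo < hi)) stop("curves have no common positive frequency range",
                         call. = FALSE)
    grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  }
  mat <- vapply(curves,
                function(cv) stats::approx(cv$freqs, cv$cum_percent,
                                           xout = grid, rule = 2)$y,
                numeric(length(grid)))
  new_cumulative(grid, rowMeans(mat))
}

#' Point-percentage change of a cumulative PSD curve
#'
#' `pct_change[i] = 100 * (C[i+1] - C[i]) / C[i]`, reported at the upper bin
#' edge. A rising tail in this series signals new fast dynamics (e.g. the
#' 2-day peak of daily symptom data). Bins whose previous cumulative value
#' is zero are omitted.
#'
#' @param cum A [cumulative_psd()] with at least 2 points.
#' @return Object of class `pct_change_series` with `freqs` and `pct_change`.
#' @export
pct_change <- function(cum) {
  stopifnot(inherits(cum, "cumulative_psd"))
  n <- length(cum$freqs)
  if (n < 2) stop("need at least 2 cumulative points", call. = FALSE)
  prev <- cum$cum_percent[-n]
  ok <- prev > 0
  structure(list(freqs = cum$freqs[-1][ok],
                 pct_change = 100 * diff(cum$cum_percent)[ok] / prev[ok]),
            class = "pct_change_series")
}

#' @export
print.pct_change_series <- function(x, ...) {
  cat(sprintf("<pct_change_series> %d bins over [%.4g, %.4g] cycles/day\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Log-log slope of a cumulative PSD curve
#'
#' Ordinary least-squares slope of `log10(cum_percent)` on `log10(freq)`
#' restricted to frequencies faster than `f_min`. A slope near 1 means the
#' cumulative power still grows almost proportionally with frequency over
#' the fitted range; a flatter slope means high-frequency components add
#' little.
#'
#' @param cum A [cumulative_psd()].
#' @param f_min Lower frequency bound, cycles/day (default 1/30, i.e. faster
#'   than monthly).
#' @return The slope (a single number).
#' @export
loglog_slope <- function(cum, f_min = 1 / 30) {
  stopifnot(inherits(cum, "cumulative_psd"))
  sel <- cum$freqs > f_min & cum$cum_percent > 0
  if (sum(sel) < 3) {
    stop(sprintf("need >= 3 points with frequency > %g and positive cumulative power",
                 f_min), call. = FALSE)
  }
  lx <- log10(cum$freqs[sel])
  ly <- log10(cum$cum_percent[sel])
  unname(stats::coef(stats::lm(ly ~ lx))[2])
}

#' Folded (aliased) frequency after sampling
#'
#' A component at `f_true` cycles/day observed with `f_s` samples/day
#' appears at `|f_true - f_s * round(f_true / f_s)|`, always inside
#' `[0, f_s/2]`.
#'
#' @param f_true True frequency, cycles/day (>= 0).
#' @param f_s Sampling rate, samples/day (> 0).
#' @return Apparent frequency in cycles/day.
#' @export
alias_frequency <- function(f_true, f_s) {
  if (any(f_true < 0)) stop_field("f_true", "must be >= 0")
  if (any(f_s <= 0)) stop_field("f_s", "must be > 0")
  abs(f_true - f_s * round(f_true / f_s))
}

#' Downsample a series to a coarser interval
#'
#' Keeps the observations nearest to the new grid `t0 + k * interval_days`;
#' used with [alias_frequency()] to demonstrate aliasing distortion.
#'
#' @param series An [ema_series()].
#' @param interval_days New sampling interval, at least the native spacing.
#' @return An [ema_series()] with nominal interval `interval_days`.
#' @export
downsample_series <- function(series, interval_days) {
  stopifnot(inherits(series, "ema_series"))
  if (interval_days < series$interval - 1e-12) {
    stop_field("interval_days", "must be at least the native sampling interval")
  }
  t0 <- series$times[1]
  n_new <- floor((series$times[length(series$times)] - t0) / interval_days) + 1
  targets <- t0 + (seq_len(n_new) - 1) * interval_days
  idx <- unique(vapply(targets,
                       function(tt) which.min(abs(series$times - tt)),
                       integer(1)))
  ema_series(series$participant_id, series$times[idx], series$values[idx],
             series$scale_min, series$scale_max, item = series$item,
             interval = interval_days)
}

#' Nyquist frequency and minimum resolvable period for a sampling interval
#'
#' @param sampling_interval_days Sampling interval in days (> 0).
#' @return List with `f_nyquist` (cycles/day, `1/(2*interval)`) and
#'   `min_resolvable_period` (days, `2*interval`).
#' @export
nyquist_limit <- function(sampling_interval_days) {
  if (!is.finite(sampling_interval_days) || sampling_interval_days <= 0) {
    stop_field("sampling_interval_days", "must be > 0")
  }
  list(f_nyquist = 1 / (2 * sampling_interval_days),
       min_resolvable_period = 2 * sampling_interval_days)
}
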