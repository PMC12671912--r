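new_knee <- function(frequency, method, params = list(), found = TRUE) {
  structure(list(frequency = frequency, method = method,
                 method_params = params, found = found),
            class = "knee_estimate")
}

#' @export
print.knee_estimate <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<knee_estimate> %.4g cycles/day (%s): %s\n",
                x$frequency, x$method, describe_frequency(x$frequency)))
  } else {
    cat(sprintf("<knee_estimate> no knee found (%s)\n", x$method))
  }
  invisible(x)
}

#' Kneedle knee point of a cumulative PSD curve
#'
#' Implements the Kneedle construction for a concave-increasing curve:
#' frequency and cumulative percent are min-max normalized, the difference
#' curve `y_n - x_n` is formed, and the knee is the frequency maximizing it.
#' If the maximum difference does not exceed `sensitivity` times the mean
#' normalized x-step (as for a straight line), an explicit "no knee" result
#' is returned. On the linear axis the curve is anchored at the origin
#' (0 cycles/day, 0 percent), where the DC-excluded cumulative spectrum
#' conceptually starts; without the anchor a knee sitting in the very first
#' resolved bin would be normalized away.
#'
#' @param cum A [cumulative_psd()] with at least 5 points.
#' @param sensitivity Kneedle sensitivity parameter (default 1).
#' @param axis Run on `"linear"` (default) or `"log"` frequency axis.
#' @return A `knee_estimate`; check `$found`.
#' @export
knee_kneedle <- function(cum, sensitivity = 1, axis = c("linear", "log")) {
  stopifnot(inherits(cum, "cumulative_psd"))
  axis <- match.arg(axis)
  if (length(cum$freqs) < 5) stop("need at least 5 curve points", call. = FALSE)
  f <- cum$freqs
  y <- cum$cum_percent
  if (axis == "linear") {
    f <- c(0, f)
    y <- c(0, y)
    x <- f
  } else {
    x <- log10(f)
  }
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- yn - xn
  i <- which.max(d)
  threshold <- sensitivity * mean(diff(xn))
  if (d[i] <= threshold || f[i] <= 0) {
    return(new_knee(NA_real_, "kneedle",
                    list(sensitivity = sensitivity, axis = axis), found = FALSE))
  }
  new_knee(f[i], "kneedle", list(sensitivity = sensitivity, axis = axis))
}

#' Second-derivative knee point
#'
#' Smooths the cumulative curve with a moving average, computes the discrete
#' second derivative of cumulative percent with respect to log-frequency on
#' the (possibly uneven) grid, and returns the frequency of maximum downward
#' curvature -- where the curve bends from steep to shallow growth. Curves
#' with negligible curvature (constant or straight) yield "no knee".
#'
#' @param cum A [cumulative_psd()] with at least 5 points.
#' @param smooth Moving-average window length in points (odd; default 3).
#' @param min_curvature Minimum |second derivative| (percent per squared
#'   decade) regarded as a real bend.
#' @return A `knee_estimate`; check `$found`.
#' @export
knee_second_derivative <- function(cum, smooth = 3L, min_curvature = 1e-6) {
  stopifnot(inherits(cum, "cumulative_psd"))
  n <- length(cum$freqs)
  if (n < 5) stop("need at least 5 curve points", call. = FALSE)
  u <- log10(cum$freqs)
  y <- cum$cum_percent
  if (smooth > 1) {
    k <- as.integer(smooth)
    if (k %% 2L == 0L) k <- k + 1L
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    y <- as.numeric(y)
    half <- (k - 1L) %/% 2L
    y[seq_len(half)] <- cum$cum_percent[seq_len(half)]
    y[(n - half + 1L):n] <- cum$cum_percent[(n - half + 1L):n]
  }
  i <- 2:(n - 1L)
  d2 <- 2 * ((y[i + 1L] - y[i]) / (u[i + 1L] - u[i]) -
             (y[i] - y[i - 1L]) / (u[i] - u[i - 1L])) / (u[i + 1L] - u[i - 1L])
  j <- which.min(d2)
  if (!is.finite(d2[j]) || -d2[j] < min_curvature) {
    return(new_knee(NA_real_, "second_derivative",
                    list(smooth = smooth), found = FALSE))
  }
  new_knee(cum$freqs[i[j]], "second_derivative", list(smooth = smooth))
}

#' Threshold knee point
#'
#' The smallest grid frequency at which the cumulative PSD reaches
#' `threshold_percent` of total power.
#'
#' @param cum A [cumulative_psd()].
#' @param threshold_percent Threshold in (0, 100]; default 90.
#' @return A `knee_estimate` (always found).
#' @export
knee_threshold <- function(cum, threshold_percent = 90) {
  stopifnot(inherits(cum, "cumulative_psd"))
  if (!is.finite(threshold_percent) || threshold_percent <= 0 ||
      threshold_percent > 100) {
    stop_field("threshold_percent", "must lie in (0, 100]")
  }
  idx <- which(cum$cum_percent >= threshold_percent - 1e-9)
  i <- if (length(idx)) idx[1] else length(cum$freqs)
  new_knee(cum$freqs[i], "threshold",
           list(threshold_percent = threshold_percent))
}

#' Nyquist-doubled sampling recommendation from a knee estimate
#'
#' By the Nyquist-Shannon criterion, sampling faster than twice the highest
#' relevant frequency avoids aliasing, so the minimum recommended sampling
#' frequency is twice the knee frequency; the corresponding maximum
#' between-prompt interval is floored to whole days (a knee at 0.03
#' cycles/day doubles to 0.06/day, i.e. a prompt at least every 16 days).
#'
#' @param knee A `knee_estimate` with a finite frequency.
#' @return Object of class `sampling_recommendation` with
#'   `min_sampling_frequency` (cycles/day), `max_interval_days` (whole days)
#'   and `source_knee`.
#' @export
recommend_sampling <- function(knee) {
  stopifnot(inherits(knee, "knee_estimate"))
  if (!isTRUE(knee$found) || !is.finite(knee$frequency)) {
    stop("no knee was found; consider knee_threshold(), which always returns a frequency",
         call. = FALSE)
  }
  f_min <- 2 * knee$frequency
  structure(list(min_sampling_frequency = f_min,
                 max_interval_days = floor(1 / f_min),
                 source_knee = knee),
            class = "sampling_recommendation")
}

#' @export
print.sampling_recommendation <- function(x, ...) {
  cat("<sampling_recommendation>\n")
  cat(sprintf("  knee: %.4g cycles/day (%s) -- %s\n",
              x$source_knee$frequency, x$source_knee$method,
              describe_frequency(x$source_knee$frequency)))
  cat(sprintf("  minimum sampling frequency: %.4g cycles/day\n",
              x$min_sampling_frequency))
  cat(sprintf("  prompt at least every %d day(s)\n", x$max_interval_days))
  invisible(x)
}
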