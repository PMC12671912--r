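#' Fit a cohort-level EMA sampling-rate model
#'
#' The main entry point. Applies the inclusion rules, interpolates missing
#' prompts, estimates each participant's Welch PSD and cumulative power
#' curve, averages the curves onto a common log-spaced grid, locates the
#' knee of the group curve with all three objective criteria (Kneedle,
#' second-derivative, threshold), and doubles the chosen knee into a
#' Nyquist-based sampling recommendation.
#'
#' @param x An [ema_cohort()], or a long-format data frame with columns
#'   `participant_id`, `time_day`, `item`, `value` (then `scale_min` and
#'   `scale_max` are required).
#' @param item Optional item label to restrict the analysis to.
#' @param scale_min,scale_max Rating-scale bounds, used only when `x` is a
#'   data frame.
#' @param min_days,max_gap_days Inclusion rules (defaults 20 and 3 days).
#' @param params [welch_params()] controlling the PSD step.
#' @param knee_method Criterion used for the recommendation; all three are
#'   computed and reported.
#' @param threshold_percent Threshold for the threshold criterion.
#' @param n_grid Size of the common log-spaced averaging grid.
#' @return Object of class `ema_spectrum` with components `cohort`
#'   (filtered, interpolated), `psd` and `curves` (per participant),
#'   `mean_curve`, `pct_change`, `knees` (list of the three estimates),
#'   `recommendation`, `exclusions` and `call`.
#' @seealso [personalized_recommendation()] for single-person protocols.
#' @examples
#' spec <- synthetic_spec(components = list(c(1/30, 1.2, 0), c(1/14, 0.8, 1)),
#'                        noise_sd = 0.4, n_days = 60, seed = 42)
#' fit <- ema_spectrum(generate_cohort(spec, 12, between_person_sd = 0.5))
#' print(fit)
#' coef(fit)
#' @export
ema_spectrum <- function(x, item = NULL, scale_min = NULL, scale_max = NULL,
                         min_days = 20L, max_gap_days = 3L,
                         params = welch_params(),
                         knee_method = c("kneedle", "second_derivative",
                                         "threshold"),
                         threshold_percent = 90, n_grid = 256L) {
  knee_method <- match.arg(knee_method)
  if (is.data.frame(x)) {
    if (is.null(scale_min) || is.null(scale_max)) {
      stop("supply `scale_min` and `scale_max` when fitting from a data frame",
           call. = FALSE)
    }
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    utils::write.csv(x, tmp, row.names = FALSE)
    x <- read_cohort_csv(tmp, scale_min, scale_max, label = "data")
  }
  stopifnot(inherits(x, "ema_cohort"))
  if (!is.null(item)) {
    x <- ema_cohort(Filter(function(s) s$item == item, x$members),
                    label = x$label)
  }
  if (!length(x$members)) stop("no series to analyse", call. = FALSE)
  filtered <- filter_participants(x, min_days = min_days,
                                  max_gap_days = max_gap_days)
  if (!length(filtered$members)) {
    stop("no participant passes the inclusion rules", call. = FALSE)
  }
  cohort <- interpolate_cohort(filtered, max_gap_days = max_gap_days)
  psd <- lapply(cohort$members, welch_psd, params = params)
  curves <- lapply(psd, cumulative_psd)
  mean_curve <- average_cumulative(curves, n_grid = n_grid)
  knees <- list(
    kneedle = knee_kneedle(mean_curve),
    second_derivative = knee_second_derivative(mean_curve),
    threshold = knee_threshold(mean_curve, threshold_percent)
  )
  chosen <- knees[[knee_method]]
  fallback <- FALSE
  if (!isTRUE(chosen$found)) {
    chosen <- knees$threshold
    fallback <- TRUE
  }
  rec <- recommend_sampling(chosen)
  rec$fallback <- fallback
  structure(list(cohort = cohort, psd = psd, curves = curves,
                 mean_curve = mean_curve, pct_change = pct_change(mean_curve),
                 knees = knees, knee_method = knee_method,
                 recommendation = rec,
                 exclusions = attr(filtered, "exclusions"),
                 params = params, call = match.call()),
            class = "ema_spectrum")
}

#' @export
print.ema_spectrum <- function(x, ...) {
  cat("EMA sampling-rate spectrum fit\n")
  cat(sprintf("  participants analysed: %d (of %d series; %d excluded)\n",
              length(x$cohort$members), nrow(x$exclusions),
              sum(!x$exclusions$retained)))
  cat("  knee estimates (cycles/day):\n")
  for (k in x$knees) {
    cat(sprintf("    %-18s %s\n", k$method,
                if (k$found) sprintf("%.4g", k$frequency) else "no knee"))
  }
  r <- x$recommendation
  cat(sprintf("  recommendation (%s%s): sample at >= %.4g cycles/day, i.e. at least every %d day(s)\n",
              r$source_knee$method, if (r$fallback) ", fallback" else "",
              r$min_sampling_frequency, r$max_interval_days))
  invisible(x)
}

#' @export
summary.ema_spectrum <- function(object, ...) {
  per <- do.call(rbind, lapply(seq_along(object$curves), function(i) {
    cv <- object$curves[[i]]
    kn <- knee_kneedle(cv)
    data.frame(participant_id = object$psd[[i]]$participant_id,
               n_points = length(object$cohort$members[[i]]$times),
               knee_frequency = if (kn$found) kn$frequency else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(fit = object, per_participant = per,
              knee_dispersion = stats::sd(per$knee_frequency, na.rm = TRUE))
  class(out) <- "summary.ema_spectrum"
  out
}

#' @export
print.summary.ema_spectrum <- function(x, ...) {
  print(x$fit)
  kf <- x$per_participant$knee_frequency
  cat(sprintf("  per-participant Kneedle knees: median %.4g, IQR [%.4g, %.4g] cycles/day (SD %.4g, %d/%d found)\n",
              stats::median(kf, na.rm = TRUE),
              stats::quantile(kf, 0.25, na.rm = TRUE),
              stats::quantile(kf, 0.75, na.rm = TRUE),
              x$knee_dispersion, sum(!is.na(kf)), length(kf)))
  invisible(x)
}

#' @export
coef.ema_spectrum <- function(object, ...) {
  vapply(object$knees, function(k) if (k$found) k$frequency else NA_real_,
         numeric(1))
}

#' Plot an EMA spectrum fit
#'
#' Two panels: the mean cumulative PSD on a log frequency axis with the
#' per-participant curves in grey and the knee estimates marked, and the
#' point-percentage change series revealing emergent fast dynamics.
#'
#' @param x An `ema_spectrum` fit.
#' @param which Panels to draw (`1`, `2`, or `c(1, 2)`).
#' @param ... Ignored.
#' @export
plot.ema_spectrum <- function(x, which = c(1, 2), ...) {
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op), add = TRUE)
  }
  if (1 %in% which) {
    graphics::plot(x$mean_curve$freqs, x$mean_curve$cum_percent, type = "n",
                   log = "x", xlab = "frequency (cycles/day)",
                   ylab = "cumulative PSD (%)", ylim = c(0, 100),
                   main = "Cumulative PSD")
    for (cv in x$curves) {
      graphics::lines(cv$freqs, cv$cum_percent,
                      col = grDevices::adjustcolor("red", 0.25))
    }
    graphics::lines(x$mean_curve$freqs, x$mean_curve$cum_percent,
                    col = "grey20", lwd = 2)
    cols <- c(kneedle = "blue", second_derivative = "darkgreen",
              threshold = "purple")
    for (k in x$knees) {
      if (k$found) graphics::abline(v = k$frequency, col = cols[[k$method]],
                                    lty = 2)
    }
    graphics::legend("bottomright", legend = names(cols), col = cols,
                     lty = 2, bty = "n", cex = 0.8)
  }
  if (2 %in% which) {
    graphics::plot(x$pct_change$freqs, x$pct_change$pct_change, type = "l",
                   log = "x", xlab = "frequency (cycles/day)",
                   ylab = "point percentage change (%)",
                   main = "Cumulative PSD increments")
  }
  invisible(x)
}
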