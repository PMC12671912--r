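knee_by_method <- function(cum, method = c("kneedle", "second_derivative",
                                           "threshold"), ...) {
  method <- match.arg(method)
  switch(method,
         kneedle = knee_kneedle(cum, ...),
         second_derivative = knee_second_derivative(cum, ...),
         threshold = knee_threshold(cum, ...))
}

#' Personalized sampling recommendation from a high-frequency baseline
#'
#' One person's pass through the stepwise protocol: the baseline series is
#' checked against the inclusion rules, truncated to its longest valid run,
#' interpolated onto the prompt grid, spectrally decomposed with Welch's
#' method, summarized as a cumulative PSD, and the chosen knee criterion is
#' doubled into a sampling recommendation. When the chosen criterion reports
#' "no knee", the 90% threshold criterion is used instead and the fallback
#' is recorded in the result (`$fallback`).
#'
#' @param baseline An [ema_series()] of densely sampled baseline data.
#' @param knee_method `"kneedle"`, `"second_derivative"` or `"threshold"`.
#' @param min_days,max_gap_days Inclusion rules (defaults 20 and 3).
#' @param params [welch_params()] for the PSD step.
#' @return A [recommend_sampling()] result with an added `fallback` flag and
#'   the participant id.
#' @export
personalized_recommendation <- function(baseline,
                                        knee_method = c("kneedle",
                                                        "second_derivative",
                                                        "threshold"),
                                        min_days = 20L, max_gap_days = 3L,
                                        params = welch_params()) {
  stopifnot(inherits(baseline, "ema_series"))
  knee_method <- match.arg(knee_method)
  run <- longest_valid_run(baseline, max_gap_days)
  if (run$span_days < min_days) {
    stop(sprintf("baseline for %s has a longest valid run of %d day(s); need >= %d",
                 baseline$participant_id, run$span_days, min_days),
         call. = FALSE)
  }
  coh <- filter_participants(ema_cohort(list(baseline)),
                             min_days = min_days, max_gap_days = max_gap_days)
  s <- interpolate_missing(coh$members[[1]], max_gap_days = max_gap_days)
  cum <- cumulative_psd(welch_psd(s, params))
  knee <- knee_by_method(cum, knee_method)
  fallback <- FALSE
  if (!isTRUE(knee$found)) {
    knee <- knee_threshold(cum, 90)
    fallback <- TRUE
  }
  rec <- recommend_sampling(knee)
  rec$fallback <- fallback
  rec$participant_id <- baseline$participant_id
  rec
}

# Windowed-sinc (band-limited) interpolation of irregularly subsampled
# values back onto arbitrary evaluation times. Kernel weights are
# renormalized so they form a partition of unity, which tapers edge
# truncation error.
sinc_reconstruct <- function(sample_times, sample_values, eval_times,
                             interval, half_width = 16L) {
  sinc <- function(u) ifelse(abs(u) < 1e-12, 1, sin(pi * u) / (pi * u))
  mu <- mean(sample_values)
  centered <- sample_values - mu
  vapply(eval_times, function(tt) {
    u <- (tt - sample_times) / interval
    k <- which(abs(u) < half_width)
    if (!length(k)) return(NA_real_)
    w <- sinc(u[k]) * cos(pi * u[k] / (2 * half_width))^2
    s <- sum(w)
    if (abs(s) < 1e-9) s <- 1
    mu + sum(w * centered[k]) / s
  }, numeric(1))
}

#' Validate a candidate sampling interval by reconstruction
#'
#' Subsamples the baseline at `interval_days`, reconstructs the signal on
#' the native grid by linear interpolation and by band-limited
#' (windowed-sinc) interpolation, and reports the root-mean-square error
#' against the held-out baseline values, normalized by the rating-scale
#' range. A sub-Nyquist interval aliases the signal and inflates both
#' errors.
#'
#' @param baseline A uniformly sampled [ema_series()] (post-interpolation).
#' @param interval_days Candidate interval, at least the native spacing and
#'   shorter than the series span.
#' @param half_width Half-width (in subsamples) of the truncated sinc
#'   kernel.
#' @param edge_exclude_days Days excluded at each end when scoring the sinc
#'   reconstruction, where the truncated kernel's edge transient dominates
#'   (default four `interval_days`).
#' @return List with `nrmse_linear`, `nrmse_sinc` (fractions of the scale
#'   range), absolute `rmse_linear`, `rmse_sinc`, and `n_heldout`.
#' @export
validate_rate <- function(baseline, interval_days, half_width = 16L,
                          edge_exclude_days = 4 * interval_days) {
  stopifnot(inherits(baseline, "ema_series"))
  tt <- baseline$times
  if (interval_days < baseline$interval - 1e-12) {
    stop_field("interval_days", "must be at least the native sampling interval")
  }
  if (interval_days >= (tt[length(tt)] - tt[1])) {
    stop_field("interval_days", "must be shorter than the series span")
  }
  sub <- downsample_series(baseline, interval_days)
  held <- which(!(tt %in% sub$times))
  if (!length(held)) {   # interval == native spacing: nothing held out
    return(list(nrmse_linear = 0, nrmse_sinc = 0, rmse_linear = 0,
                rmse_sinc = 0, n_heldout = 0L))
  }
  rng <- baseline$scale_max - baseline$scale_min
  lin <- stats::approx(sub$times, sub$values, xout = tt[held], rule = 2)$y
  rmse_lin <- sqrt(mean((lin - baseline$values[held])^2))
  interior <- held[tt[held] >= tt[1] + edge_exclude_days &
                   tt[held] <= tt[length(tt)] - edge_exclude_days]
  if (!length(interior)) interior <- held
  bl <- sinc_reconstruct(sub$times, sub$values, tt[interior], interval_days,
                         half_width = half_width)
  rmse_sinc <- sqrt(mean((bl - baseline$values[interior])^2))
  list(nrmse_linear = rmse_lin / rng, nrmse_sinc = rmse_sinc / rng,
       rmse_linear = rmse_lin, rmse_sinc = rmse_sinc,
       n_heldout = length(held))
}

#' Subgroup summaries of personalized recommendations
#'
#' Runs [personalized_recommendation()] for every cohort member and
#' aggregates per labelled subgroup (e.g. diagnosis or severity strata).
#'
#' @param cohort An [ema_cohort()] of baseline series.
#' @param labels Named character vector mapping participant ids to group
#'   labels; every participant must be labelled.
#' @param knee_method Knee criterion passed to
#'   [personalized_recommendation()].
#' @param ... Further arguments for [personalized_recommendation()].
#' @return List with `per_participant` (id, group, knee frequency, method,
#'   interval, fallback) and `by_group` (group, n, mean/SD knee frequency,
#'   modal recommended interval).
#' @export
subgroup_recommendations <- function(cohort, labels,
                                     knee_method = "kneedle", ...) {
  stopifnot(inherits(cohort, "ema_cohort"))
  ids <- cohort_ids(cohort)
  unlabeled <- setdiff(ids, names(labels))
  if (length(unlabeled)) {
    stop(sprintf("unlabeled participant(s): %s",
                 paste(unlabeled, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(cohort$members, function(s) {
    rec <- personalized_recommendation(s, knee_method = knee_method, ...)
    data.frame(participant_id = s$participant_id,
               group = unname(labels[s$participant_id]),
               knee_frequency = rec$source_knee$frequency,
               method = rec$source_knee$method,
               interval_days = rec$max_interval_days,
               fallback = rec$fallback,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  empty <- setdiff(unique(unname(labels)), unique(per$group))
  if (length(empty)) {
    warning(sprintf("group(s) with no participants omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  modal <- function(x) as.numeric(names(sort(table(x), decreasing = TRUE))[1])
  by_group <- do.call(rbind, lapply(split(per, per$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               mean_knee = mean(g$knee_frequency),
               sd_knee = stats::sd(g$knee_frequency),
               modal_interval_days = modal(g$interval_days),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  list(per_participant = per, by_group = by_group)
}
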