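#' Specification for a synthetic EMA signal
#'
#' Defines the generative model used by [generate_series()]: a baseline level
#' plus a sum of sinusoidal components (e.g. monthly, biweekly and weekly
#' symptom cycles), additive white Gaussian noise, optional 1/f (pink) noise,
#' clipping to the declared rating scale and optional Likert rounding, and
#' bounded-gap missingness.
#'
#' @param components Sinusoidal components: a data frame (or list of length-3
#'   vectors) with columns `frequency` (cycles/day), `amplitude` (rating
#'   units) and `phase` (radians).
#' @param baseline Mean rating level, in rating units.
#' @param noise_sd Standard deviation of white Gaussian noise added before
#'   clipping/quantization.
#' @param pink_sd Standard deviation of an optional 1/f-shaped noise
#'   component (0 disables it). Lets tests probe non-flat spectral
#'   backgrounds.
#' @param n_days Number of days covered by the schedule.
#' @param samples_per_day Scheduled prompts per day (1 = daily, 4 = four
#'   times daily).
#' @param scale_min,scale_max Rating scale bounds.
#' @param quantize If `TRUE`, emitted values are rounded to integer Likert
#'   steps after clipping; if `FALSE` (VAS-style) values are only clipped.
#' @param missing_prob Probability that a scheduled prompt goes unanswered.
#' @param max_gap_run Longest run of fully-missing days the generator is
#'   allowed to create.
#' @param daytime_window If `TRUE` and `samples_per_day > 1`, prompts are
#'   placed evenly inside a 12-hour daytime window (09:00-21:00), mirroring
#'   designs that never prompt at night; if `FALSE` prompts are spread
#'   uniformly over the 24-hour day.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   identical series.
#' @param alias_demo Set `TRUE` to permit component frequencies at or above
#'   the schedule's Nyquist frequency (for aliasing demonstrations only).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(components = NULL, baseline = 4, noise_sd = 0,
                           pink_sd = 0, n_days = 30, samples_per_day = 1,
                           scale_min = 1, scale_max = 7, quantize = TRUE,
                           missing_prob = 0, max_gap_run = 3,
                           daytime_window = TRUE, seed = 1L,
                           alias_demo = FALSE) {
  components <- normalize_components(components)
  if (!is_count(n_days)) stop_field("n_days", "must be an integer >= 1")
  if (!is_count(samples_per_day)) {
    stop_field("samples_per_day", "must be a positive integer")
  }
  if (!is.finite(scale_min) || !is.finite(scale_max) || scale_min >= scale_max) {
    stop_field("scale_min", "requires scale_min < scale_max")
  }
  if (!is.finite(missing_prob) || missing_prob < 0 || missing_prob >= 1) {
    stop_field("missing_prob", "must satisfy 0 <= missing_prob < 1")
  }
  if (!is_count(max_gap_run)) stop_field("max_gap_run", "must be an integer >= 1")
  if (!is.finite(noise_sd) || noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (!is.finite(pink_sd) || pink_sd < 0) stop_field("pink_sd", "must be >= 0")
  if (nrow(components)) {
    if (any(!is.finite(components$frequency)) || any(components$frequency <= 0)) {
      stop_field("components", "frequencies must be positive and finite")
    }
    if (any(components$amplitude < 0)) {
      stop_field("components", "amplitudes must be >= 0")
    }
    f_nyq <- samples_per_day / 2
    if (!alias_demo && any(components$frequency >= f_nyq)) {
      stop_field("components",
                 sprintf("frequencies must be < samples_per_day/2 = %g cycles/day (set alias_demo = TRUE for aliasing demonstrations)",
                         f_nyq))
    }
  }
  structure(
    list(components = components, baseline = baseline, noise_sd = noise_sd,
         pink_sd = pink_sd, n_days = as.integer(n_days),
         samples_per_day = as.integer(samples_per_day),
         scale_min = scale_min, scale_max = scale_max, quantize = quantize,
         missing_prob = missing_prob, max_gap_run = as.integer(max_gap_run),
         daytime_window = daytime_window, seed = as.integer(seed),
         alias_demo = alias_demo),
    class = "synthetic_spec"
  )
}

normalize_components <- function(components) {
  if (is.null(components)) {
    return(data.frame(frequency = numeric(), amplitude = numeric(),
                      phase = numeric()))
  }
  if (is.list(components) && !is.data.frame(components)) {
    components <- do.call(rbind, lapply(components, function(cmp) {
      cmp <- as.numeric(cmp)
      if (length(cmp) == 2) cmp <- c(cmp, 0)
      if (length(cmp) != 3) {
        stop_field("components", "each component needs (frequency, amplitude, phase)")
      }
      data.frame(frequency = cmp[1], amplitude = cmp[2], phase = cmp[3])
    }))
  }
  components <- as.data.frame(components)
  if (!all(c("frequency", "amplitude") %in% names(components))) {
    stop_field("components", "needs columns `frequency` and `amplitude`")
  }
  if (is.null(components$phase)) components$phase <- 0
  components[, c("frequency", "amplitude", "phase")]
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d day(s) x %d prompt(s)/day, scale [%g, %g] (%s)\n",
              x$n_days, x$samples_per_day, x$scale_min, x$scale_max,
              if (x$quantize) "Likert" else "VAS"))
  cat(sprintf("  %d sinusoidal component(s), noise_sd %g, pink_sd %g, missing_prob %g, seed %d\n",
              nrow(x$components), x$noise_sd, x$pink_sd, x$missing_prob, x$seed))
  invisible(x)
}

# Scheduled prompt times, in days from study start.
prompt_times <- function(spec) {
  days <- rep(seq_len(spec$n_days) - 1L, each = spec$samples_per_day)
  if (spec$samples_per_day == 1L) {
    offsets <- 0
  } else if (spec$daytime_window) {
    # evenly spaced inside 09:00-21:00
    offsets <- 9 / 24 + (seq_len(spec$samples_per_day) - 1L) *
      (12 / 24) / (spec$samples_per_day - 1L)
  } else {
    offsets <- (seq_len(spec$samples_per_day) - 1L) / spec$samples_per_day
  }
  days + rep(offsets, times = spec$n_days)
}

# 1/f-amplitude noise via spectral shaping, normalized to unit sd.
pink_noise <- function(n) {
  if (n < 4) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- c(1, seq_len(n - 1))              # guard DC
  X <- X / sqrt(k)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate one synthetic EMA series
#'
#' Evaluates the deterministic signal `baseline + sum(amplitude *
#' sin(2*pi*frequency*t + phase))` on the prompt schedule, adds noise, clips
#' to the rating scale, optionally rounds to Likert steps, and removes
#' prompts according to the missingness model. Identical seeds give
#' identical output.
#'
#' @param spec A [synthetic_spec()].
#' @param participant_id,item Labels for the resulting series.
#' @return An [ema_series()].
#' @export
generate_series <- function(spec, participant_id = "P1", item = "item") {
  stopifnot(inherits(spec, "synthetic_spec"))
  t <- prompt_times(spec)
  y <- rep(spec$baseline, length(t))
  if (nrow(spec$components)) {
    for (i in seq_len(nrow(spec$components))) {
      cmp <- spec$components[i, ]
      y <- y + cmp$amplitude * sin(2 * pi * cmp$frequency * t + cmp$phase)
    }
  }
  seeds <- derive_seeds(spec$seed, 3L)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(seeds[1], stats::rnorm(length(t), sd = spec$noise_sd))
  }
  if (spec$pink_sd > 0) {
    y <- y + spec$pink_sd * with_seed(seeds[2], pink_noise(length(t)))
  }
  y <- pmin(pmax(y, spec$scale_min), spec$scale_max)
  if (spec$quantize) y <- round(y)
  out <- ema_series(participant_id, t, y, spec$scale_min, spec$scale_max,
                    item = item, interval = 1 / spec$samples_per_day)
  if (spec$missing_prob > 0) {
    out <- inject_missingness(out, spec$missing_prob, spec$max_gap_run,
                              seed = seeds[3])
  }
  out
}

#' Remove prompts at random while bounding missing-day runs
#'
#' Drops each prompt independently with probability `missing_prob`, then
#' repairs the mask so that no run of consecutive fully-missing days exceeds
#' `max_gap_run` (one randomly chosen prompt of the offending day is
#' restored). Observed values are never altered.
#'
#' @param series An [ema_series()] with no missing prompts.
#' @param missing_prob Per-prompt missingness probability in `[0, 1)`.
#' @param max_gap_run Longest permitted run of fully-missing days.
#' @param seed Integer seed for the missingness mask.
#' @return An [ema_series()] with a subset of the input prompts.
#' @export
inject_missingness <- function(series, missing_prob, max_gap_run = 3L,
                               seed = 1L) {
  stopifnot(inherits(series, "ema_series"))
  if (!is.finite(missing_prob) || missing_prob < 0 || missing_prob >= 1) {
    stop_field("missing_prob", "must satisfy 0 <= missing_prob < 1")
  }
  if (missing_prob == 0) return(series)
  n <- length(series$times)
  keep <- with_seed(seed, {
    keep <- stats::runif(n) >= missing_prob
    day <- floor(series$times)
    days <- sort(unique(day))
    run <- 0L
    for (d in days) {
      idx <- which(day == d)
      if (any(keep[idx])) {
        run <- 0L
      } else {
        run <- run + 1L
        if (run > max_gap_run) {
          keep[idx[sample.int(length(idx), 1L)]] <- TRUE
          run <- 0L
        }
      }
    }
    keep
  })
  ema_series(series$participant_id, series$times[keep], series$values[keep],
             series$scale_min, series$scale_max, item = series$item,
             interval = series$interval)
}

#' Generate a synthetic EMA cohort
#'
#' Independent participants drawn from a common [synthetic_spec()].
#' Between-person heterogeneity enters through the baseline (additive
#' Gaussian spread), optionally through a multiplicative spread of component
#' amplitudes, and optionally through per-person random phases. With
#' `n_participants = 1` and all spreads at zero the result is identical to
#' `generate_series(spec)`.
#'
#' @param spec A [synthetic_spec()]; participant `i` uses seed `seed + i - 1`.
#' @param n_participants Number of participants (>= 1).
#' @param between_person_sd SD of per-person baseline offsets, rating units.
#' @param seed Master seed for the cohort (defaults to `spec$seed`).
#' @param amplitude_sd SD of per-person multiplicative amplitude factors
#'   (factor = `max(0, 1 + N(0, amplitude_sd))`). A single value applies one
#'   common factor to all components; a vector (one entry per component)
#'   draws an independent factor per component, so inflating a single
#'   entry inflates between-person variance in that frequency band only --
#'   the variance-inflation knob for contrasting cohorts. Note that a common
#'   factor cancels from per-person normalized cumulative curves.
#' @param random_phase If `TRUE`, each participant receives independent
#'   uniform component phases, decorrelating participants' cycles.
#' @param label Cohort label.
#' @param item Item label shared by all members.
#' @return An [ema_cohort()].
#' @export
generate_cohort <- function(spec, n_participants, between_person_sd = 0,
                            seed = spec$seed, amplitude_sd = 0,
                            random_phase = FALSE, label = "synthetic",
                            item = "item") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is_count(n_participants)) {
    stop_field("n_participants", "must be an integer >= 1")
  }
  aux_seeds <- derive_seeds(seed, 3L)
  offsets <- if (between_person_sd > 0) {
    with_seed(aux_seeds[1], stats::rnorm(n_participants, sd = between_person_sd))
  } else rep(0, n_participants)
  n_cmp <- max(1L, nrow(spec$components))
  if (length(amplitude_sd) == 1L) {
    amplitude_sd <- rep(amplitude_sd, n_cmp)
  } else if (length(amplitude_sd) != n_cmp) {
    stop_field("amplitude_sd", "must have length 1 or one entry per component")
  }
  amp_fac <- if (any(amplitude_sd > 0)) {
    with_seed(aux_seeds[2], {
      m <- 1 + sweep(matrix(stats::rnorm(n_participants * n_cmp),
                            nrow = n_participants), 2, amplitude_sd, `*`)
      m[m < 0] <- 0
      m
    })
  } else matrix(1, n_participants, n_cmp)
  phases <- if (random_phase && nrow(spec$components)) {
    with_seed(aux_seeds[3],
              matrix(stats::runif(n_participants * nrow(spec$components),
                                  0, 2 * pi),
                     nrow = n_participants))
  } else NULL
  members <- lapply(seq_len(n_participants), function(i) {
    s <- spec
    s$seed <- as.integer((seed + i - 1) %% .Machine$integer.max)
    s$baseline <- spec$baseline + offsets[i]
    if (nrow(s$components)) {
      s$components$amplitude <- s$components$amplitude *
        amp_fac[i, seq_len(nrow(s$components))]
      if (!is.null(phases)) s$components$phase <- phases[i, ]
    }
    generate_series(s, participant_id = sprintf("P%03d", i), item = item)
  })
  ema_cohort(members, label = label)
}

#' Generate a multi-item synthetic cohort
#'
#' Each participant carries one latent symptom trajectory (the generating
#' spec's deterministic signal plus person-level noise); each item is that latent
#' trajectory plus independent item-level noise, then clipped/quantized.
#' This emulates a questionnaire whose items track a common underlying
#' symptom process, as needed for composite and symptom-count analyses.
#'
#' @inheritParams generate_cohort
#' @param items Character vector of item labels.
#' @param item_noise_sd SD of item-specific noise around the latent signal.
#' @return An [ema_cohort()] with `length(items)` series per participant.
#' @export
generate_multi_item_cohort <- function(spec, n_participants, items,
                                       between_person_sd = 0,
                                       item_noise_sd = 0.5,
                                       seed = spec$seed,
                                       label = "synthetic-items") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(items) || anyDuplicated(items)) {
    stop_field("items", "must be a non-empty vector of unique labels")
  }
  if (!is_count(n_participants)) {
    stop_field("n_participants", "must be an integer >= 1")
  }
  t <- prompt_times(spec)
  aux <- derive_seeds(seed, 1L + n_participants)
  offsets <- if (between_person_sd > 0) {
    with_seed(aux[1], stats::rnorm(n_participants, sd = between_person_sd))
  } else rep(0, n_participants)
  members <- vector("list", n_participants * length(items))
  k <- 0L
  for (i in seq_len(n_participants)) {
    latent <- rep(spec$baseline + offsets[i], length(t))
    if (nrow(spec$components)) {
      for (j in seq_len(nrow(spec$components))) {
        cmp <- spec$components[j, ]
        latent <- latent + cmp$amplitude *
          sin(2 * pi * cmp$frequency * t + cmp$phase)
      }
    }
    person_seeds <- derive_seeds(aux[1L + i], 1L + length(items))
    if (spec$noise_sd > 0) {
      latent <- latent + with_seed(person_seeds[1],
                                   stats::rnorm(length(t), sd = spec$noise_sd))
    }
    for (j in seq_along(items)) {
      y <- latent
      if (item_noise_sd > 0) {
        y <- y + with_seed(person_seeds[1L + j],
                           stats::rnorm(length(t), sd = item_noise_sd))
      }
      y <- pmin(pmax(y, spec$scale_min), spec$scale_max)
      if (spec$quantize) y <- round(y)
      k <- k + 1L
      members[[k]] <- ema_series(sprintf("P%03d", i), t, y,
                                 spec$scale_min, spec$scale_max,
                                 item = items[j],
                                 interval = 1 / spec$samples_per_day)
    }
  }
  ema_cohort(members, label = label)
}
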