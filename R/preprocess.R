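#' Read a long-format EMA cohort from CSV
#'
#' Expects columns `participant_id`, `time_day`, `item`, `value` (UTF-8,
#' header required). Rows whose value falls outside the declared scale, or
#' whose time/value is not numeric, are dropped with a warning; the dropped
#' rows (with their file line numbers) are attached as attribute
#' `"rejected"`.
#'
#' @param path Path to the CSV file.
#' @param scale_min,scale_max Declared rating scale bounds used for
#'   validation.
#' @param label Cohort label (defaults to the file name).
#' @return An [ema_cohort()]; one series per (participant, item).
#' @export
read_cohort_csv <- function(path, scale_min, scale_max, label = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "time_day", "item", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  tm <- suppressWarnings(as.numeric(df$time_day))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- !is.finite(tm) | !is.finite(val) |
    val < scale_min - 1e-9 | val > scale_max + 1e-9
  rejected <- data.frame(line = line[bad],
                         participant_id = df$participant_id[bad],
                         time_day = df$time_day[bad],
                         item = df$item[bad],
                         value = df$value[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("%d malformed/out-of-scale row(s) dropped (lines %s)",
                    nrow(rejected),
                    paste(utils::head(rejected$line, 10), collapse = ", ")),
            call. = FALSE)
  }
  df <- df[!bad, , drop = FALSE]
  tm <- tm[!bad]; val <- val[!bad]
  key <- interaction(df$participant_id, df$item, drop = TRUE, lex.order = TRUE)
  members <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    o <- idx[order(tm[idx])]
    ema_series(df$participant_id[o[1]], tm[o], val[o], scale_min, scale_max,
               item = df$item[o[1]])
  })
  out <- ema_cohort(unname(members), label = label)
  attr(out, "rejected") <- rejected
  out
}

#' Write a cohort as long-format CSV
#'
#' @param cohort An [ema_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ema_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Longest contiguous span with bounded missing-day gaps
#'
#' A day counts as observed when at least one of its prompts was answered.
#' A valid run is a span from an observed day to an observed day in which
#' every run of consecutive fully-missing days has length at most
#' `max_gap_days`; such gaps are bridged and their days count toward the
#' span. Ties between equal-length runs keep the earliest.
#'
#' @param series An [ema_series()].
#' @param max_gap_days Longest bridgeable run of fully-missing days.
#' @return A list with `start_day`, `end_day` (integer day indices, i.e.
#'   `floor(time)`), `span_days` (end - start + 1) and `n_observed_days`.
#' @export
longest_valid_run <- function(series, max_gap_days = 3L) {
  stopifnot(inherits(series, "ema_series"))
  if (!length(series$times)) {
    return(list(start_day = NA_integer_, end_day = NA_integer_,
                span_days = 0L, n_observed_days = 0L))
  }
  days <- sort(unique(as.integer(floor(series$times))))
  gaps <- diff(days) - 1L
  breaks <- which(gaps > max_gap_days)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(days))
  spans <- days[ends] - days[starts] + 1L
  best <- which.max(spans)          # which.max keeps the earliest on ties
  list(start_day = days[starts[best]], end_day = days[ends[best]],
       span_days = as.integer(spans[best]),
       n_observed_days = ends[best] - starts[best] + 1L)
}

#' Apply inclusion rules and truncate members to their longest valid run
#'
#' Retains participants whose longest valid run (gaps of at most
#' `max_gap_days` fully-missing days are bridged) spans at least `min_days`
#' days, and truncates each retained series to that run. The exclusion log is
#' attached as attribute `"exclusions"` (participant_id, item, retained,
#' longest_run_days, reason).
#'
#' @param cohort An [ema_cohort()].
#' @param min_days Minimum valid-run span in days (default 20).
#' @param max_gap_days Longest bridgeable missing-day run (default 3).
#' @return Filtered [ema_cohort()] (possibly empty).
#' @export
filter_participants <- function(cohort, min_days = 20L, max_gap_days = 3L) {
  stopifnot(inherits(cohort, "ema_cohort"))
  log <- vector("list", length(cohort$members))
  kept <- vector("list", length(cohort$members))
  for (i in seq_along(cohort$members)) {
    s <- cohort$members[[i]]
    run <- longest_valid_run(s, max_gap_days)
    ok <- run$span_days >= min_days
    log[[i]] <- data.frame(
      participant_id = s$participant_id, item = s$item, retained = ok,
      longest_run_days = run$span_days,
      reason = if (ok) "" else
        sprintf("longest valid run %d day(s) < %d", run$span_days, min_days),
      stringsAsFactors = FALSE)
    if (ok) {
      day <- floor(s$times)
      sel <- day >= run$start_day & day <= run$end_day
      kept[[i]] <- ema_series(s$participant_id, s$times[sel], s$values[sel],
                              s$scale_min, s$scale_max, item = s$item,
                              interval = s$interval)
    }
  }
  out <- ema_cohort(Filter(Negate(is.null), kept), label = cohort$label)
  attr(out, "exclusions") <- do.call(rbind, log)
  out
}

#' Linearly interpolate missing prompts onto the scheduled grid
#'
#' Regularizes the series onto its nominal prompt grid (spacing
#' `series$interval` starting at the first observation) and fills missing
#' slots by linear interpolation between the bracketing observations.
#' Observed values are kept unchanged and nothing is extrapolated beyond the
#' first/last observation. The series must already be truncated to a valid
#' run; an internal fully-missing-day gap longer than `max_gap_days`
#' triggers an error (filter first).
#'
#' @param series An [ema_series()].
#' @param max_gap_days Longest internal missing-day gap tolerated.
#' @return An [ema_series()] on the full scheduled grid.
#' @export
interpolate_missing <- function(series, max_gap_days = 3L) {
  stopifnot(inherits(series, "ema_series"))
  n <- length(series$times)
  if (n < 2) return(series)
  run <- longest_valid_run(series, max_gap_days)
  day <- as.integer(floor(series$times))
  if (run$start_day > min(day) || run$end_day < max(day)) {
    stop("series contains a fully-missing-day gap longer than `max_gap_days`; apply filter_participants() first",
         call. = FALSE)
  }
  step <- series$interval
  t0 <- series$times[1]
  slots <- as.integer(round((series$times - t0) / step))
  if (anyDuplicated(slots)) {
    stop("observations are closer together than the nominal interval; cannot regularize",
         call. = FALSE)
  }
  n_slots <- slots[n] + 1L
  values <- rep(NA_real_, n_slots)
  values[slots + 1L] <- series$values
  if (anyNA(values)) {
    filled <- stats::approx(x = which(!is.na(values)), y = values[!is.na(values)],
                            xout = seq_len(n_slots), method = "linear")$y
    values[is.na(values)] <- filled[is.na(values)]
  }
  ema_series(series$participant_id, t0 + (seq_len(n_slots) - 1L) * step,
             values, series$scale_min, series$scale_max, item = series$item,
             interval = step)
}

# Interpolate every member of a cohort.
interpolate_cohort <- function(cohort, max_gap_days = 3L) {
  ema_cohort(lapply(cohort$members, interpolate_missing,
                    max_gap_days = max_gap_days),
             label = cohort$label)
}

#' Pointwise-mean composite score across items
#'
#' For each participant owning all requested items at aligned times, returns
#' one composite series equal to the pointwise mean of the item values (e.g.
#' the mean of the two PHQ-2 items). Participants missing an item, or with
#' misaligned prompt times, are dropped and logged in attribute
#' `"dropped"`.
#'
#' @param cohort An [ema_cohort()] whose members carry item labels.
#' @param items Character vector of item labels to average.
#' @param name Label for the composite series.
#' @return An [ema_cohort()] with one composite series per participant.
#' @export
composite_score <- function(cohort, items, name = paste(items, collapse = "+")) {
  stopifnot(inherits(cohort, "ema_cohort"))
  if (!length(items)) stop_field("items", "must be non-empty")
  ids <- cohort_ids(cohort)
  dropped <- character()
  members <- list()
  for (id in ids) {
    own <- Filter(function(s) s$participant_id == id && s$item %in% items,
                  cohort$members)
    got <- vapply(own, `[[`, character(1), "item")
    if (!all(items %in% got)) {
      dropped <- c(dropped, id)
      next
    }
    own <- own[match(items, got)]
    times <- own[[1]]$times
    aligned <- all(vapply(own, function(s) {
      length(s$times) == length(times) && all(abs(s$times - times) < 1e-9)
    }, logical(1)))
    if (!aligned) {
      dropped <- c(dropped, id)
      next
    }
    vals <- rowMeans(do.call(cbind, lapply(own, `[[`, "values")))
    members[[length(members) + 1L]] <-
      ema_series(id, times, vals, own[[1]]$scale_min, own[[1]]$scale_max,
                 item = name, interval = own[[1]]$interval)
  }
  if (length(dropped)) {
    warning(sprintf("%d participant(s) dropped from composite '%s': %s",
                    length(dropped), name,
                    paste(utils::head(dropped, 10), collapse = ", ")),
            call. = FALSE)
  }
  out <- ema_cohort(members, label = cohort$label)
  attr(out, "dropped") <- dropped
  out
}
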