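#' Construct an EMA series
#'
#' An `ema_series` holds one participant's timestamped ratings for one item
#' (or composite) on a declared rating scale. Times are real-valued days and
#' must be strictly increasing; prompts that were never answered are simply
#' absent from the series rather than stored as `NA`.
#'
#' @param participant_id Participant identifier (coerced to character).
#' @param times Numeric vector of observation times in days, strictly
#'   increasing.
#' @param values Numeric ratings, same length as `times`, each within
#'   `[scale_min, scale_max]`.
#' @param scale_min,scale_max Bounds of the rating scale (e.g. 1 and 7 for a
#'   Likert item, 0 and 100 for a VAS item).
#' @param item Item label (single item or composite name).
#' @param interval Nominal sampling interval in days (e.g. 1 for daily
#'   prompts, 0.25 for four prompts per day). Inferred from the median time
#'   step when omitted.
#' @return An object of class `ema_series`.
#' @export
ema_series <- function(participant_id, times, values, scale_min, scale_max,
                       item = "item", interval = NULL) {
  participant_id <- as.character(participant_id)[1]
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop_field("values", "must have the same length as `times`")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_field("times", "must be strictly increasing")
  }
  if (!is.finite(scale_min) || !is.finite(scale_max) || scale_min >= scale_max) {
    stop_field("scale_min", "requires scale_min < scale_max")
  }
  if (length(values) && (any(!is.finite(values)) ||
                         any(values < scale_min - 1e-9) ||
                         any(values > scale_max + 1e-9))) {
    stop_field("values", sprintf("all values must lie in [%g, %g]",
                                 scale_min, scale_max))
  }
  if (is.null(interval)) {
    interval <- if (length(times) > 1) stats::median(diff(times)) else 1
  }
  if (!is.finite(interval) || interval <= 0) {
    stop_field("interval", "must be a positive number of days")
  }
  structure(
    list(participant_id = participant_id, times = times, values = values,
         scale_min = scale_min, scale_max = scale_max, item = item,
         interval = interval),
    class = "ema_series"
  )
}

#' @export
print.ema_series <- function(x, ...) {
  cat(sprintf("<ema_series> participant %s, item '%s'\n", x$participant_id, x$item))
  cat(sprintf("  %d observations over days [%.3g, %.3g], scale [%g, %g], nominal interval %g day(s)\n",
              length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              x$scale_min, x$scale_max, x$interval))
  invisible(x)
}

#' @export
as.data.frame.ema_series <- function(x, ...) {
  data.frame(participant_id = rep(x$participant_id, length(x$times)),
             time_day = x$times,
             item = rep(x$item, length(x$times)),
             value = x$values,
             stringsAsFactors = FALSE)
}

#' Construct an EMA cohort
#'
#' A cohort is a labelled collection of [ema_series()] objects. Each
#' (participant, item) pair must be unique; a participant may contribute
#' several items (e.g. the 21 symptom ratings used for composite analyses).
#'
#' @param members List of `ema_series` objects.
#' @param label Cohort label.
#' @return Object of class `ema_cohort`.
#' @export
ema_cohort <- function(members, label = "cohort") {
  if (!is.list(members) || (length(members) &&
      !all(vapply(members, inherits, logical(1), "ema_series")))) {
    stop_field("members", "must be a list of ema_series objects")
  }
  keys <- vapply(members, function(s) paste(s$participant_id, s$item, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    stop_field("members", "duplicated (participant_id, item) pairs")
  }
  structure(list(label = label, members = members), class = "ema_cohort")
}

#' @export
print.ema_cohort <- function(x, ...) {
  ids <- unique(vapply(x$members, `[[`, character(1), "participant_id"))
  items <- unique(vapply(x$members, `[[`, character(1), "item"))
  cat(sprintf("<ema_cohort> '%s': %d series, %d participants, %d item(s)\n",
              x$label, length(x$members), length(ids), length(items)))
  invisible(x)
}

#' @export
length.ema_cohort <- function(x) length(x$members)

#' @export
as.data.frame.ema_cohort <- function(x, ...) {
  if (!length(x$members)) {
    return(data.frame(participant_id = character(), time_day = numeric(),
                      item = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$members, as.data.frame))
}

cohort_ids <- function(cohort) {
  unique(vapply(cohort$members, `[[`, character(1), "participant_id"))
}

cohort_items <- function(cohort) {
  unique(vapply(cohort$members, `[[`, character(1), "item"))
}
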