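test_that("cohort CSV round-trips and invalid rows are rejected with line numbers", {
  spec <- synthetic_spec(components = list(c(1 / 14, 1, 0)), baseline = 4,
                         noise_sd = 0.5, n_days = 30, scale_min = 1,
                         scale_max = 7, missing_prob = 0.1, seed = 21)
  coh <- generate_cohort(spec, 5, between_person_sd = 0.4, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path, 1, 7, label = coh$label)
  expect_equal(length(back$members), length(coh$members))
  ids <- vapply(coh$members, `[[`, character(1), "participant_id")
  back_by_id <- setNames(back$members,
                         vapply(back$members, `[[`, character(1), "participant_id"))
  for (i in seq_along(coh$members)) {
    expect_equal(back_by_id[[ids[i]]]$times, coh$members[[i]]$times)
    expect_equal(back_by_id[[ids[i]]]$values, coh$members[[i]]$values)
  }

  # two-row minimal file
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_day,item,value",
               "A,0,mood,3", "A,1,mood,5"), tiny)
  tc <- read_cohort_csv(tiny, 1, 7)
  expect_length(tc$members, 1)
  expect_equal(tc$members[[1]]$values, c(3, 5))

  # out-of-scale value dropped and reported
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_day,item,value",
               "A,0,mood,3", "A,1,mood,9", "A,2,mood,4"), bad)
  expect_warning(bc <- read_cohort_csv(bad, 1, 7), "1 malformed")
  expect_equal(nrow(attr(bc, "rejected")), 1)
  expect_equal(attr(bc, "rejected")$line, 3)
  expect_equal(bc$members[[1]]$values, c(3, 4))

  # missing column is a hard failure naming the column
  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,time_day,value", "A,0,3"), nocol)
  expect_error(read_cohort_csv(nocol, 1, 7), "item")
})

test_that("longest_valid_run bridges short gaps and splits on long ones", {
  mk <- function(days) ema_series("P", days, rep(4, length(days)), 1, 7,
                                  interval = 1)
  # 30 consecutive observed days
  r <- longest_valid_run(mk(1:30), 3)
  expect_equal(r$span_days, 30)
  # days 1-15 observed, 16-19 missing (4-day gap), 20-34 observed:
  # the gap exceeds 3 so the run splits; both halves span 15, earliest kept
  r <- longest_valid_run(mk(c(1:15, 20:34)), 3)
  expect_equal(r$span_days, 15)
  expect_equal(r$start_day, 1)
  expect_equal(r$end_day, 15)
  # days 1-10, 13-25 observed: the 2-day gap bridges into one 25-day run
  r <- longest_valid_run(mk(c(1:10, 13:25)), 3)
  expect_equal(r$span_days, 25)
  expect_equal(r$n_observed_days, 23)
  # empty series
  r <- longest_valid_run(mk(numeric(0)), 3)
  expect_equal(r$span_days, 0)
})

test_that("filter_participants enforces the 20-day rule and truncates to the run", {
  mk <- function(id, days) ema_series(id, days, rep(4, length(days)), 1, 7,
                                      interval = 1)
  coh <- ema_cohort(list(
    mk("short19", 1:19),              # 19 consecutive days: excluded
    mk("gap4", c(1:15, 20:34)),       # longest valid run 15: excluded
    mk("bridged", c(1:10, 13:25)),    # 25-day bridged run: retained
    mk("long", 1:40)))                # retained
  out <- filter_participants(coh, min_days = 20, max_gap_days = 3)
  ids <- vapply(out$members, `[[`, character(1), "participant_id")
  expect_setequal(ids, c("bridged", "long"))
  log <- attr(out, "exclusions")
  expect_equal(sum(!log$retained), 2)
  expect_match(log$reason[log$participant_id == "gap4"], "15")
  # filtering is idempotent
  twice <- filter_participants(out, min_days = 20, max_gap_days = 3)
  expect_equal(as.data.frame(twice), as.data.frame(out))
})

test_that("interpolation fills the scheduled grid without touching observations", {
  # midpoint example: day 2 missing between values 2 and 4
  s <- ema_series("P", c(1, 3), c(2, 4), 1, 7, interval = 1)
  out <- interpolate_missing(s)
  expect_equal(out$times, c(1, 2, 3))
  expect_equal(out$values, c(2, 3, 4))
  # identity on complete series
  full <- make_sine_series(n_days = 30)
  expect_equal(interpolate_missing(full)$values, full$values)
  # observed points conserved, interpolants bounded by bracketing values
  spec <- synthetic_spec(components = list(c(1 / 14, 1.5, 0)), baseline = 4,
                         noise_sd = 0.6, n_days = 60, scale_min = 1,
                         scale_max = 7, missing_prob = 0.25, seed = 31)
  m <- generate_series(spec)
  out <- interpolate_missing(m)
  idx <- match(round(m$times, 9), round(out$times, 9))
  expect_false(anyNA(idx))
  expect_equal(out$values[idx], m$values)
  filled <- setdiff(seq_along(out$times), idx)
  for (j in filled) {
    lo <- max(idx[idx < j]); hi <- min(idx[idx > j])
    expect_gte(out$values[j], min(out$values[lo], out$values[hi]) - 1e-9)
    expect_lte(out$values[j], max(out$values[lo], out$values[hi]) + 1e-9)
  }
  # over-long internal gap is rejected
  gappy <- ema_series("P", c(1:10, 16:30), rep(4, 25), 1, 7, interval = 1)
  expect_error(interpolate_missing(gappy), "filter_participants")
})

test_that("composite scores average aligned items and single items copy through", {
  t <- 0:9
  mk <- function(id, item, v) ema_series(id, t, v, 1, 7, item = item,
                                         interval = 1)
  coh <- ema_cohort(list(mk("A", "mood", rep(2, 10)),
                         mk("A", "anhedonia", rep(4, 10)),
                         mk("B", "mood", rep(5, 10))))
  comp <- suppressWarnings(composite_score(coh, c("mood", "anhedonia"),
                                           name = "phq2"))
  expect_length(comp$members, 1)   # B lacks anhedonia and is dropped
  expect_equal(attr(comp, "dropped"), "B")
  expect_true(all(comp$members[[1]]$values == 3))
  expect_equal(comp$members[[1]]$item, "phq2")
  single <- composite_score(coh, "mood", name = "mood-copy")
  expect_length(single$members, 2)
  expect_equal(single$members[[1]]$values, rep(2, 10))
})
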