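# Classic (mean-centered) Levene test: one-way ANOVA on |x - group mean|.
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  ctr <- if (center == "mean") {
    stats::ave(values, groups, FUN = mean)
  } else {
    stats::ave(values, groups, FUN = stats::median)
  }
  z <- abs(values - ctr)
  fit <- stats::anova(stats::lm(z ~ groups))
  W <- fit[["F value"]][1]
  p <- fit[["Pr(>F)"]][1]
  if (!is.finite(W)) { W <- 0; p <- 1 }
  list(statistic = W, p_value = p,
       df = c(fit[["Df"]][1], fit[["Df"]][2]))
}

#' Frequency-wise Levene tests of between-cohort variance
#'
#' For every shared frequency bin inside `band`, tests whether the spread of
#' per-participant point-percentage changes differs between the two cohorts
#' (classic mean-centered Levene by default; `center = "median"` gives the
#' Brown-Forsythe variant). P-values are Bonferroni-multiplied by the number
#' of bins tested inside the band.
#'
#' @param a,b Lists of [pct_change()] series, one per participant, all on an
#'   identical frequency grid; each cohort needs at least 2 members (3+
#'   recommended).
#' @param band Length-2 numeric `(low, high)` in cycles/day delimiting the
#'   bins tested (inclusive).
#' @param alpha Significance level applied to adjusted p-values.
#' @param center Deviation center for the Levene statistic.
#' @return Object of class `cohort_comparison`: a per-bin table
#'   (`frequency`, `statistic`, `p_raw`, `p_adj`, `significant`), the number
#'   of bins tested, and the Pearson correlation of the two cohorts' mean
#'   point-percentage curves over the full shared grid.
#' @export
levene_by_frequency <- function(a, b, band, alpha = 0.05,
                                center = c("mean", "median")) {
  center <- match.arg(center)
  check_pct_list <- function(lst, nm) {
    if (length(lst) < 2) {
      stop(sprintf("cohort `%s` needs at least 2 members", nm), call. = FALSE)
    }
    stopifnot(all(vapply(lst, inherits, logical(1), "pct_change_series")))
  }
  check_pct_list(a, "a"); check_pct_list(b, "b")
  grid <- a[[1]]$freqs
  same_grid <- function(lst) all(vapply(lst, function(s) {
    length(s$freqs) == length(grid) && all(abs(s$freqs - grid) < 1e-9)
  }, logical(1)))
  if (!same_grid(a) || !same_grid(b)) {
    stop("all series must share an identical frequency grid (resample first)",
         call. = FALSE)
  }
  if (length(band) != 2 || band[1] >= band[2]) {
    stop_field("band", "must be (low, high) with low < high")
  }
  bins <- which(grid >= band[1] - 1e-12 & grid <= band[2] + 1e-12)
  if (!length(bins)) stop("no frequency bins inside the band", call. = FALSE)
  ma <- vapply(a, `[[`, numeric(length(grid)), "pct_change")
  mb <- vapply(b, `[[`, numeric(length(grid)), "pct_change")
  res <- lapply(bins, function(i) {
    vals <- c(ma[i, ], mb[i, ])
    grp <- rep(c("a", "b"), c(ncol(ma), ncol(mb)))
    lv <- levene_test(vals, grp, center = center)
    data.frame(frequency = grid[i], statistic = lv$statistic,
               p_raw = lv$p_value)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- pmin(1, tab$p_raw * nrow(tab))
  tab$significant <- tab$p_adj < alpha
  r <- suppressWarnings(stats::cor(rowMeans(ma), rowMeans(mb)))
  structure(list(table = tab, band = band, n_bins_tested = nrow(tab),
                 curve_correlation = r, alpha = alpha, center = center),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d bin(s) in [%.4g, %.4g] cycles/day, Levene (%s-centered)\n",
              x$n_bins_tested, x$band[1], x$band[2], x$center))
  cat(sprintf("  significant after Bonferroni at alpha=%g: %d bin(s); mean-curve r = %.3f\n",
              x$alpha, sum(x$table$significant), x$curve_correlation))
  invisible(x)
}

#' Pearson correlation of two cumulative PSD curves
#'
#' @param a,b [cumulative_psd()] curves on an identical frequency grid
#'   (resample with [resample_cumulative()] if needed).
#' @return Pearson r, or `NA` (with a warning) when a curve is constant.
#' @export
curve_correlation <- function(a, b) {
  stopifnot(inherits(a, "cumulative_psd"), inherits(b, "cumulative_psd"))
  if (length(a$freqs) != length(b$freqs) ||
      any(abs(a$freqs - b$freqs) > 1e-9)) {
    stop("curves must share the same frequency grid; use resample_cumulative()",
         call. = FALSE)
  }
  if (stats::sd(a$cum_percent) == 0 || stats::sd(b$cum_percent) == 0) {
    warning("correlation undefined for a constant curve", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a$cum_percent, b$cum_percent)
}

#' Effect of symptom count on the cumulative PSD slope
#'
#' For each requested count, randomly selects that many items (seeded),
#' forms per-participant composite scores, runs the per-person Welch /
#' cumulative-PSD pipeline, averages across participants, and reports the
#' log-log slope of the group curve above `f_min`. When the count equals the
#' number of available items the subset is exhaustive and the result is
#' deterministic.
#'
#' @param cohort Multi-item [ema_cohort()] (every participant must carry all
#'   items).
#' @param counts Item-subset sizes to evaluate (default `c(2, 5, 9, 14, 21)`).
#' @param seed Integer seed governing item selection.
#' @param f_min Lower frequency bound for the slope fit (default 1/30).
#' @param params [welch_params()] used per participant.
#' @return Data frame with columns `count`, `slope` and `items`
#'   (comma-separated labels used).
#' @export
symptom_count_analysis <- function(cohort, counts = c(2, 5, 9, 14, 21),
                                   seed = 1L, f_min = 1 / 30,
                                   params = welch_params()) {
  stopifnot(inherits(cohort, "ema_cohort"))
  items <- cohort_items(cohort)
  if (any(counts > length(items))) {
    stop(sprintf("requested count exceeds the %d available items",
                 length(items)), call. = FALSE)
  }
  seeds <- derive_seeds(seed, length(counts))
  out <- lapply(seq_along(counts), function(k) {
    cnt <- counts[k]
    sel <- if (cnt == length(items)) items else {
      with_seed(seeds[k], sample(items, cnt))
    }
    comp <- suppressWarnings(
      composite_score(cohort, sel, name = sprintf("composite-%d", cnt)))
    curves <- lapply(comp$members, function(s) cumulative_psd(welch_psd(s, params)))
    avg <- average_cumulative(curves)
    data.frame(count = cnt, slope = loglog_slope(avg, f_min = f_min),
               items = paste(sel, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
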