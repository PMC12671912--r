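# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

# n reproducible sub-seeds derived from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1

# Human-readable period for a frequency in cycles/day.
describe_frequency <- function(f) {
  if (!is.finite(f) || f <= 0) return("no fluctuation (constant level)")
  period <- 1 / f
  if (period >= 1) {
    sprintf("fluctuations completing a cycle about every %.3g days", period)
  } else {
    sprintf("fluctuations completing a cycle about every %.3g hours", period * 24)
  }
}
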