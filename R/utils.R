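# internal helpers shared across modules

# upper-tail hypergeometric p for an observed overlap:
# P(X >= overlap) with X ~ Hypergeom(universe, |b|, draws = |a|)
hyper_upper_p <- function(overlap, size_a, size_b, universe) {
  if (overlap > min(size_a, size_b)) {
    abort("overlap exceeds set sizes; inconsistent inputs")
  }
  if (size_a > universe || size_b > universe) {
    abort("set sizes exceed the universe")
  }
  stats::phyper(overlap - 1, size_b, universe - size_b, size_a, lower.tail = FALSE)
}

# circular difference in hours on a cycle of length `period`, result in
# (-period/2, period/2]
circular_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# circular mean of hours on a cycle of length `period`, mapped to [0, period)
circular_mean <- function(h, period = 24) {
  ang <- 2 * pi * h / period
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (m * period / (2 * pi)) %% period
}

# circular median of absolute deviations is taken on the already-folded
# differences, so plain median applies downstream

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
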