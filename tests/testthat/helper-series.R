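# Shared fixtures and an independent model-selection oracle.

make_series <- function(days, values, id = "s1") {
  measurement_series(id, days, values)
}

# Straight-line series with given noise, single segment (all gaps < 183 d).
random_single_segment <- function(n, noise_sd = 2) {
  days <- cumsum(c(1L, sample(1:120, n - 1L, replace = TRUE)))
  k <- sample(seq_len(min(4L, n - 1L)), 1L)
  u <- (days - days[1]) / max(days[length(days)] - days[1], 1)
  beta <- stats::rnorm(k + 1, sd = 10)
  y <- drop(outer(u, 0:k, `^`) %*% beta) + stats::rnorm(n, 0, noise_sd)
  make_series(days, y)
}

# From-scratch selection oracle, independent of the package internals: full
# stats::lm() fits per order, stats::AIC() for the likelihood-based criterion
# (same floor rule for degenerate zero-rss fits), argmin with first-minimum
# (lowest order) tie-break. Candidate set re-derived from the documented
# sparsity rules.
oracle_select_order <- function(days, values,
                                forced_linear_below_n = 8L, max_order = 4L) {
  n <- length(days)
  cands <- if (n < forced_linear_below_n) 1L else
    seq_len(min(max_order, n - 1L))
  u <- (days - days[1]) / (days[n] - days[1])
  d <- data.frame(u = u, y = values)
  floor_val <- max(1e-12 * n * stats::var(values),
                   1e-20 * n * max(mean(values^2), 1), 1e-300)
  aics <- vapply(cands, function(p) {
    fit <- stats::lm(y ~ poly(u, degree = p, raw = TRUE), data = d)
    rss <- sum(stats::residuals(fit)^2)
    if (rss <= floor_val) {
      n * log(2 * pi) + n * log(floor_val / n) + n + 2 * (p + 2)
    } else {
      stats::AIC(fit)
    }
  }, numeric(1))
  cands[which.min(aics)]
}
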