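# Shifted Legendre polynomials on [0, 1], as power-basis coefficient vectors
# (constant term first). Used to draw ground-truth trajectories whose
# order-k component is orthogonal to all lower orders under a uniform time
# design, so "true order k" is identifiable rather than an artefact of
# near-collinear raw powers.
shifted_legendre <- list(
  c(-1, 2),
  c(1, -6, 6),
  c(-1, 12, -30, 20),
  c(1, -20, 90, -140, 70)
)

#' Generative settings for a synthetic longitudinal cohort
#'
#' Describes a cohort of irregularly sampled series with known polynomial
#' ground truth, emulating the structure of routine paediatric lung-function
#' records: per-subject measurement counts drawn uniformly on 2-150, visit
#' gaps gamma-distributed with mean 53 days and clamped to 1-365 days (so
#' essentially all consecutive gaps fall within 6 months), outcome values on
#' a %-predicted-like scale centred near 70, and i.i.d. Gaussian measurement
#' noise (default sd 5 units, a typical within-person short-term variability
#' for FEV1 % predicted).
#'
#' @param n_subjects Number of subjects.
#' @param n_range Inclusive range of per-subject measurement counts, drawn
#'   discrete-uniformly; use `c(n, n)` to pin the count.
#' @param gap_mean Mean gap between consecutive visits, days.
#' @param gap_shape Gamma shape for the gap distribution (scale is
#'   `gap_mean / gap_shape`).
#' @param gap_range Gaps are rounded and clamped into this range (days).
#' @param gap_dist `"gamma"` or `"constant"` (every gap `round(gap_mean)`).
#' @param order_probs Probabilities for true polynomial orders 1-4.
#' @param baseline Outcome level the trajectory is centred on (outcome units).
#' @param signal_range Range of the noise-free trajectory over the subject's
#'   span (outcome units); coefficients are rescaled to hit it exactly.
#' @param noise_sd Measurement noise standard deviation (outcome units).
#' @param seed Integer seed; subjects get deterministic sub-streams.
#' @param outcome_label Label attached to generated series.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L,
                        n_range = c(2L, 150L),
                        gap_mean = 53,
                        gap_shape = 2,
                        gap_range = c(1L, 365L),
                        gap_dist = c("gamma", "constant"),
                        order_probs = rep(0.25, 4),
                        baseline = 70,
                        signal_range = 20,
                        noise_sd = 5,
                        seed = 1L,
                        outcome_label = "FEV1 % predicted") {
  gap_dist <- match.arg(gap_dist)
  stopifnot(n_subjects >= 0, length(n_range) == 2, n_range[1] >= 1,
            n_range[1] <= n_range[2], gap_mean > 0, gap_shape > 0,
            length(gap_range) == 2, gap_range[1] >= 1,
            gap_range[1] <= gap_range[2],
            length(order_probs) == 4, all(order_probs >= 0),
            sum(order_probs) > 0, signal_range >= 0, noise_sd >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_range = as.integer(n_range), gap_mean = gap_mean,
         gap_shape = gap_shape, gap_range = as.integer(gap_range),
         gap_dist = gap_dist, order_probs = order_probs / sum(order_probs),
         baseline = baseline, signal_range = signal_range,
         noise_sd = noise_sd, seed = as.integer(seed),
         outcome_label = outcome_label),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects, n per subject %d-%d, %s gaps (mean %.0f d, clamped %d-%d)\n",
              x$n_subjects, x$n_range[1], x$n_range[2], x$gap_dist,
              x$gap_mean, x$gap_range[1], x$gap_range[2]))
  cat(sprintf("  truth: orders 1-4 w.p. (%s), baseline %.0f, signal range %.0f, noise sd %.1f, seed %d\n",
              paste(format(x$order_probs), collapse = ", "), x$baseline,
              x$signal_range, x$noise_sd, x$seed))
  invisible(x)
}

# Evaluate a ground-truth polynomial (power-basis coefficients on scaled
# time) at raw days.
truth_eval <- function(coefficients, time_scaling, days) {
  u <- (as.numeric(days) - time_scaling[["offset"]]) / time_scaling[["range"]]
  drop(outer(u, seq_along(coefficients) - 1, `^`) %*% coefficients)
}

#' Evaluate a subject's ground truth at given days
#'
#' @param truth A `ground_truth` from [generate_subject()].
#' @param days Days on the raw axis.
#' @return Numeric vector of noise-free outcome values.
#' @export
true_values <- function(truth, days) {
  stopifnot(inherits(truth, "ground_truth"))
  truth_eval(truth$coefficients, truth$time_scaling, days)
}

#' Generate one synthetic subject with known ground truth
#'
#' Visit days are day 1 plus cumulative gaps. The true trajectory is a
#' polynomial of a drawn order k, built in the shifted-Legendre basis with
#' per-component weights drawn from +/-[0.5, 1] so the leading-order
#' component is never negligible, then rescaled so its range over the daily
#' span equals `signal_range` and shifted so its mean equals `baseline`.
#' Observations are the truth at visit days plus Gaussian noise. Output is
#' deterministic given `(spec$seed, subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Positive integer identifying the subject's RNG
#'   stream.
#' @return List with `series` (a [measurement_series()]) and `truth` (class
#'   `ground_truth`: true `order`, power-basis `coefficients` on scaled time,
#'   `time_scaling`, `noise_sd`, `grid_days`, `true_daily_values`).
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"), subject_index >= 1)
  sid <- sprintf("S%04d", subject_index)
  with_local_rng(subject_seed(spec$seed, subject_index), {
    n <- if (spec$n_range[1] == spec$n_range[2]) spec$n_range[1] else
      sample(seq.int(spec$n_range[1], spec$n_range[2]), 1L)
    gaps <- if (n < 2L) integer(0) else switch(
      spec$gap_dist,
      constant = rep(as.integer(round(spec$gap_mean)), n - 1L),
      gamma = pmin(pmax(as.integer(round(stats::rgamma(
        n - 1L, shape = spec$gap_shape,
        scale = spec$gap_mean / spec$gap_shape))),
        spec$gap_range[1]), spec$gap_range[2]))
    days <- as.integer(1 + c(0, cumsum(gaps)))
    k <- sample(1:4, 1L, prob = spec$order_probs)
    if (n >= 2L) {
      scaling <- c(offset = as.numeric(days[1]),
                   range = as.numeric(days[n] - days[1]))
      b <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.5, 1)
      coefs <- numeric(k + 1)
      for (j in seq_len(k)) {
        lj <- shifted_legendre[[j]]
        coefs[seq_along(lj)] <- coefs[seq_along(lj)] + b[j] * lj
      }
      grid <- seq.int(days[1], days[n])
      g <- truth_eval(coefs, scaling, grid)
      rng <- diff(range(g))
      if (spec$signal_range > 0 && rng > 0) coefs <- coefs * spec$signal_range / rng
      g <- truth_eval(coefs, scaling, grid)
      coefs[1] <- coefs[1] + spec$baseline - mean(g)
      true_daily <- truth_eval(coefs, scaling, grid)
    } else {
      scaling <- c(offset = as.numeric(days[1]), range = 1)
      coefs <- spec$baseline
      grid <- days
      true_daily <- spec$baseline
    }
    y <- truth_eval(coefs, scaling, days) + stats::rnorm(n, 0, spec$noise_sd)
    list(
      series = measurement_series(sid, days, y,
                                  outcome_label = spec$outcome_label),
      truth = structure(
        list(subject_id = sid, order = k, coefficients = coefs,
             time_scaling = scaling, noise_sd = spec$noise_sd,
             grid_days = grid, true_daily_values = true_daily),
        class = "ground_truth"))
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (named list of [measurement_series()]) and
#'   `truths` (named list of `ground_truth`).
#' @seealso [cohort_structure_summary()] to check the realised sampling
#'   structure against the declared distributions.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subs <- lapply(seq_len(spec$n_subjects), function(i)
    generate_subject(spec, i))
  cohort <- lapply(subs, `[[`, "series")
  truths <- lapply(subs, `[[`, "truth")
  names(cohort) <- names(truths) <-
    vapply(cohort, `[[`, character(1), "subject_id")
  list(cohort = cohort, truths = truths)
}

#' Realised sampling structure of a cohort
#'
#' @param cohort List of [measurement_series()].
#' @return List: `n_subjects`, `n_measurements` (total),
#'   `mean_n_per_subject`, `range_n`, `mean_gap_days`, `range_gap_days`,
#'   `frac_gaps_within_6mo` (fraction of consecutive gaps <= 183 days).
#' @export
cohort_structure_summary <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  ns <- vapply(cohort, function(s) length(s$days), integer(1))
  gaps <- unlist(lapply(cohort, function(s)
    if (length(s$days) > 1) diff(s$days) else integer(0)))
  list(n_subjects = length(cohort),
       n_measurements = sum(ns),
       mean_n_per_subject = mean(ns),
       range_n = range(ns),
       mean_gap_days = if (length(gaps)) mean(gaps) else NA_real_,
       range_gap_days = if (length(gaps)) range(gaps) else c(NA, NA),
       frac_gaps_within_6mo = if (length(gaps)) mean(gaps <= 183) else NA_real_)
}

#' Generate a daily exposure series over a subject's span
#'
#' Stand-in for densely captured remote-monitoring data (e.g. daily step
#' count): a positive AR(1) process with one value per day from the subject's
#' first to last measurement day. Deterministic given `seed`.
#'
#' @param series A [measurement_series()] defining the span.
#' @param mean Long-run exposure mean (exposure units).
#' @param sd Marginal standard deviation of the process.
#' @param phi AR(1) autocorrelation in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `day`, `value`.
#' @export
generate_exposure <- function(series, mean = 5000, sd = 500, phi = 0.6,
                              seed = 1L) {
  stopifnot(inherits(series, "measurement_series"),
            phi >= 0, phi < 1, sd >= 0)
  days <- seq.int(series$days[1], series$days[length(series$days)])
  with_local_rng(seed, {
    e <- numeric(length(days))
    e[1] <- mean + stats::rnorm(1, 0, sd)
    innov_sd <- sd * sqrt(1 - phi^2)
    for (t in seq_along(days)[-1]) {
      e[t] <- mean + phi * (e[t - 1] - mean) + stats::rnorm(1, 0, innov_sd)
    }
    data.frame(subject_id = series$subject_id, day = as.integer(days),
               value = pmax(e, 0), stringsAsFactors = FALSE)
  })
}
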