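#' Observed-versus-predicted residual summary
#'
#' Compares every measurement against the selected fit of the segment it
#' belongs to. Observations in unmodelled (singleton) segments are counted as
#' uncovered and reported, never silently dropped. The investigation
#' threshold identifies large absolute discrepancies worth inspecting as
#' potential within-person outliers (default 20 outcome units, i.e.
#' percentage points for a %-predicted outcome).
#'
#' @param models A `trajectory_model` or list of them.
#' @param investigation_threshold Absolute residual above which an observation
#'   is counted as an exceedance (outcome units; default 20).
#' @return List of class `residual_summary`: `observations` (one row per
#'   covered measurement: `subject_id`, `day`, `observed`, `predicted`,
#'   `abs_diff`), `per_subject` (mean/sd/min/max of `abs_diff` plus exceedance
#'   counts), and `cohort` (the same aggregates over all observations, plus
#'   `n_obs` and `n_uncovered`).
#' @export
residual_summary <- function(models, investigation_threshold = 20) {
  if (inherits(models, "trajectory_model")) models <- list(models)
  stopifnot(length(models) > 0,
            all(vapply(models, inherits, logical(1), "trajectory_model")))
  obs <- list()
  n_uncovered <- 0L
  for (m in models) {
    for (s in m$segments) {
      if (is.null(s$fit)) {
        n_uncovered <- n_uncovered + length(s$segment$days)
        next
      }
      pred <- evaluate_fit(s$fit, s$segment$days)
      obs[[length(obs) + 1L]] <- data.frame(
        subject_id = m$subject_id, day = s$segment$days,
        observed = s$segment$values, predicted = pred,
        abs_diff = abs(s$segment$values - pred), stringsAsFactors = FALSE)
    }
  }
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(subject_id = character(0), day = integer(0),
               observed = numeric(0), predicted = numeric(0),
               abs_diff = numeric(0))
  rownames(observations) <- NULL
  agg <- function(d) {
    data.frame(mean_abs = mean(d$abs_diff), sd_abs = stats::sd(d$abs_diff),
               min_abs = min(d$abs_diff), max_abs = max(d$abs_diff),
               n_exceed = sum(d$abs_diff > investigation_threshold),
               n_obs = nrow(d))
  }
  per_subject <- do.call(rbind, lapply(split(observations,
                                             observations$subject_id), agg))
  if (!is.null(per_subject)) {
    per_subject <- cbind(subject_id = rownames(per_subject), per_subject)
    rownames(per_subject) <- NULL
  }
  cohort <- if (nrow(observations) > 0) as.list(agg(observations)) else
    list(mean_abs = NA_real_, sd_abs = NA_real_, min_abs = NA_real_,
         max_abs = NA_real_, n_exceed = 0L, n_obs = 0L)
  cohort$frac_exceed <- if (cohort$n_obs > 0) cohort$n_exceed / cohort$n_obs else NA_real_
  cohort$n_uncovered <- n_uncovered
  cohort$investigation_threshold <- investigation_threshold
  structure(list(observations = observations, per_subject = per_subject,
                 cohort = cohort),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  c <- x$cohort
  cat(sprintf("<residual_summary> %d observations (%d uncovered)\n",
              c$n_obs, c$n_uncovered))
  if (c$n_obs > 0) {
    cat(sprintf("  mean |obs - pred| = %.2f (sd %.2f, range %.2f-%.2f)\n",
                c$mean_abs, c$sd_abs, c$min_abs, c$max_abs))
    cat(sprintf("  exceedances > %.0f units: %d (%.1f%%)\n",
                c$investigation_threshold, c$n_exceed, 100 * c$frac_exceed))
  }
  invisible(x)
}

#' Pairwise observed versus predicted change
#'
#' For every unordered pair of measurement days within the same modelled
#' segment and within `max_gap_days` of each other, records the absolute
#' observed change `|y_i - y_j|` and the absolute predicted change
#' `|yhat(day_i) - yhat(day_j)|`. On noisy data the predicted change is
#' systematically smaller: the fitted trajectory smooths measurement noise, so
#' change estimated from the model mitigates the noise in raw paired
#' measurements.
#'
#' @param model A `trajectory_model`.
#' @param max_gap_days Largest day gap between paired measurements (default
#'   183, i.e. 6 months).
#' @return Data frame with one row per qualifying pair: `subject_id`,
#'   `day_i`, `day_j`, `gap_days`, `abs_d_obs`, `abs_d_pred`.
#' @seealso [pairwise_cohort_summary()] to aggregate rows across subjects.
#' @export
pairwise_change <- function(model, max_gap_days = 183) {
  stopifnot(inherits(model, "trajectory_model"), max_gap_days > 0)
  rows <- list()
  for (s in model$segments) {
    if (is.null(s$fit)) next
    d <- s$segment$days
    y <- s$segment$values
    yhat <- evaluate_fit(s$fit, d)
    m <- length(d)
    if (m < 2L) next
    idx <- utils::combn(m, 2L)
    gap <- d[idx[2, ]] - d[idx[1, ]]
    keep <- gap > 0 & gap <= max_gap_days
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = model$subject_id,
      day_i = d[idx[1, keep]], day_j = d[idx[2, keep]],
      gap_days = gap[keep],
      abs_d_obs = abs(y[idx[2, keep]] - y[idx[1, keep]]),
      abs_d_pred = abs(yhat[idx[2, keep]] - yhat[idx[1, keep]]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), day_i = integer(0),
               day_j = integer(0), gap_days = integer(0),
               abs_d_obs = numeric(0), abs_d_pred = numeric(0))
  rownames(out) <- NULL
  out
}

#' Aggregate pairwise-change rows over a cohort
#'
#' @param pairs Data frame of rows from [pairwise_change()], typically
#'   `rbind`-ed across subjects.
#' @return List with `n_pairs` and mean/sd/min/max of the absolute observed
#'   and predicted changes.
#' @export
pairwise_cohort_summary <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    return(list(n_pairs = 0L, mean_abs_d_obs = NA_real_,
                mean_abs_d_pred = NA_real_))
  }
  list(n_pairs = nrow(pairs),
       mean_abs_d_obs = mean(pairs$abs_d_obs),
       sd_abs_d_obs = stats::sd(pairs$abs_d_obs),
       range_abs_d_obs = range(pairs$abs_d_obs),
       mean_abs_d_pred = mean(pairs$abs_d_pred),
       sd_abs_d_pred = stats::sd(pairs$abs_d_pred),
       range_abs_d_pred = range(pairs$abs_d_pred))
}

#' Stability of model selection under 80% subsampling
#'
#' Each iteration draws `ceiling(fraction * n)` of the subject's measurements
#' without replacement (day order preserved), re-runs the full conditional
#' pipeline — segmentation, candidate orders and AIC selection, with the
#' sparsity rules re-evaluated on the subsample's measurement count — and
#' records the selected order (for multi-segment subsamples, the order of the
#' longest modellable segment; `NA` when nothing is modellable). Consistency
#' is the fraction of iterations selecting the same order as the full-data
#' fit. Identical seeds reproduce identical reports.
#'
#' @param series An eligible [measurement_series()].
#' @param rules A [rule_config()].
#' @param fraction Subsample fraction in `(0, 1]` (default 0.8).
#' @param iterations Number of resampling iterations (default 100).
#' @param seed Integer seed for this subject's resampling stream.
#' @return List of class `stability_report`: `subject_id`, `original_order`,
#'   `orders` (length `iterations`), `consistency`, `fraction`, `iterations`,
#'   `seed`.
#' @export
stability_resample <- function(series, rules = rule_config(), fraction = 0.8,
                               iterations = 100L, seed = 1L) {
  stopifnot(inherits(series, "measurement_series"))
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- length(series$days)
  m <- as.integer(ceiling(fraction * n))
  if (m < 2L) stop("subsample size ", m, " < 2; series too short", call. = FALSE)
  original <- primary_order(select_trajectory(series, rules))
  orders <- integer(iterations)
  with_local_rng(seed, {
    for (it in seq_len(iterations)) {
      idx <- sort(sample.int(n, m))
      sub <- measurement_series(series$subject_id, series$days[idx],
                                series$values[idx],
                                outcome_label = series$outcome_label)
      fit <- select_trajectory(sub, rules, check_eligibility = FALSE)
      orders[it] <- primary_order(fit)
    }
  })
  structure(
    list(subject_id = series$subject_id,
         original_order = original,
         orders = orders,
         consistency = mean(!is.na(orders) & orders == original),
         fraction = fraction, iterations = as.integer(iterations),
         seed = as.integer(seed)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> subject %s: original order %d, consistency %.2f over %d iterations (%.0f%% subsamples)\n",
              x$subject_id, x$original_order, x$consistency, x$iterations,
              100 * x$fraction))
  invisible(x)
}

#' Cohort-level stability of model selection
#'
#' Runs [stability_resample()] for every subject with a per-subject seed
#' derived deterministically from `(seed, subject index)`, so the result does
#' not depend on cohort ordering effects of a shared stream.
#'
#' @param cohort List of eligible [measurement_series()].
#' @param rules A [rule_config()].
#' @param fraction,iterations As in [stability_resample()].
#' @param seed Cohort-level integer seed.
#' @param consistency_threshold Subjects at or above this consistency count as
#'   stable in the cohort summary (default 0.75).
#' @return List with `per_subject` (data frame: `subject_id`,
#'   `original_order`, `consistency`), `reports` (the full per-subject
#'   reports) and `cohort` (`mean_consistency`, `frac_above_threshold`,
#'   `n_fully_consistent`).
#' @export
stability_cohort <- function(cohort, rules = rule_config(), fraction = 0.8,
                             iterations = 100L, seed = 1L,
                             consistency_threshold = 0.75) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  reports <- lapply(seq_along(cohort), function(i) {
    stability_resample(cohort[[i]], rules, fraction, iterations,
                       seed = subject_seed(seed, i))
  })
  per_subject <- data.frame(
    subject_id = vapply(reports, `[[`, character(1), "subject_id"),
    original_order = vapply(reports, `[[`, integer(1), "original_order"),
    consistency = vapply(reports, `[[`, numeric(1), "consistency"),
    stringsAsFactors = FALSE)
  list(per_subject = per_subject,
       reports = reports,
       cohort = list(
         mean_consistency = mean(per_subject$consistency),
         frac_above_threshold = mean(per_subject$consistency >=
                                       consistency_threshold),
         n_fully_consistent = sum(per_subject$consistency == 1)))
}

#' Slope of a simple linear regression with 95% confidence interval
#'
#' Convenience utility for relating evaluation outputs to covariates (e.g.
#' pairwise change against time gap, or stability consistency against number
#' of observations).
#'
#' @param x,y Numeric vectors of equal length.
#' @param level Confidence level (default 0.95).
#' @return Named list: `slope`, `ci_low`, `ci_high`.
#' @export
fit_slope <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = level)
  list(slope = unname(stats::coef(fit)[["x"]]),
       ci_low = ci[1], ci_high = ci[2])
}
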