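#' Map integer days onto the unit interval
#'
#' Polynomial fitting uses a min-max scaled time axis
#' `u = (day - offset) / range` with `offset` the first day and `range` the
#' span, so that raising day counts in the thousands to the 4th power stays
#' well conditioned. The map is affine, so fits and predictions are invariant
#' to shifting all days by a constant.
#'
#' @param days Strictly increasing integer day indices (at least 2 distinct).
#' @return List with `u` (scaled days in `[0, 1]`) and `scaling`, a named
#'   numeric `c(offset, range)`.
#' @examples
#' scale_time(c(1, 11, 21))$u  # 0, 0.5, 1
#' @export
scale_time <- function(days) {
  days <- as.numeric(days)
  if (length(days) < 2L) stop("at least 2 days are required", call. = FALSE)
  offset <- days[1]
  rng <- days[length(days)] - days[1]
  if (rng <= 0) {
    stop("degenerate time axis: all days identical", call. = FALSE)
  }
  list(u = (days - offset) / rng,
       scaling = c(offset = offset, range = rng))
}

# Design matrix of scaled-time powers 0..order.
poly_design <- function(u, order) {
  outer(u, 0:order, `^`)
}

# Floor substituted for a (near-)zero residual sum of squares so the Gaussian
# AIC stays finite; scaled to the data so a perfect higher-order fit can never
# beat a perfect lower-order fit (the penalty term decides). The second term
# absorbs floating-point noise when the outcome is constant (variance 0), so
# exact fits of any order share one floored rss instead of being ranked by
# rounding error.
rss_floor <- function(n, values) {
  v <- if (length(values) > 1L) stats::var(values) else 0
  max(1e-12 * n * v, 1e-20 * n * max(mean(values^2), 1), 1e-300)
}

#' Gaussian AIC for an ordinary least-squares polynomial fit
#'
#' Uses the full maximum-likelihood convention for linear models,
#' `AIC = n log(2 pi) + n log(rss / n) + n + 2 (p + 2)`,
#' i.e. `-2 logL + 2k` with `k = p + 2` estimated parameters (intercept, `p`
#' slopes, and the error variance). This matches `stats::AIC()` on an `lm`
#' fit of the same model. Lower is better.
#'
#' @param fit A `polynomial_fit`, or a raw residual sum of squares.
#' @param ... Unused for the fit method.
#' @param n,order Sample size and polynomial order, required when `fit` is a
#'   numeric rss.
#' @return The AIC (a single number).
#' @examples
#' gaussian_aic(10, n = 10, order = 1)  # 34.3788...
#' @export
gaussian_aic <- function(fit, ...) UseMethod("gaussian_aic")

#' @rdname gaussian_aic
#' @export
gaussian_aic.polynomial_fit <- function(fit, ...) fit$aic

#' @rdname gaussian_aic
#' @export
gaussian_aic.numeric <- function(fit, ..., n, order) {
  rss <- fit
  stopifnot(rss > 0, n >= 1, order >= 0)
  n * log(2 * pi) + n * log(rss / n) + n + 2 * (order + 2)
}

#' Fit one polynomial of a given order to a segment
#'
#' Ordinary least squares of the outcome on powers `1..order` of min-max
#' scaled time, with intercept. When the segment has exactly `order + 1`
#' points the fit interpolates the data. A zero residual sum of squares is
#' replaced by a data-scaled floor for the AIC (see [gaussian_aic()]) and the
#' fit is marked `perfect`.
#'
#' @param segment A `trajectory_segment` (from [segment_for_modelling()]), or
#'   any list with numeric `days` and `values`.
#' @param order Polynomial order `p >= 1`; the segment must have at least
#'   `p + 1` points.
#' @return An object of class `polynomial_fit`: order, coefficients on the
#'   scaled basis (`beta0..betap`), `time_scaling`, `n`, `rss`, `sigma2_hat`,
#'   `aic`, `standard_error` (`sqrt(rss / (n - p - 1))`, `NA` when `n = p + 1`),
#'   `r_squared` (`NA` when the outcome is constant), `perfect`, and the
#'   unscaled coefficient covariance used for confidence bands.
#' @export
fit_polynomial <- function(segment, order) {
  order <- as.integer(order)
  days <- as.numeric(segment$days)
  values <- as.numeric(segment$values)
  n <- length(days)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (n < order + 1L) {
    stop(sprintf("insufficient points: order %d needs >= %d, segment has %d",
                 order, order + 1L, n), call. = FALSE)
  }
  st <- scale_time(days)
  X <- poly_design(st$u, order)
  ls <- stats::lm.fit(X, values)
  if (ls$rank < order + 1L) {
    stop("rank-deficient polynomial design (duplicate days?)", call. = FALSE)
  }
  beta <- ls$coefficients
  rss <- sum(ls$residuals^2)
  tss <- sum((values - mean(values))^2)
  floor_val <- rss_floor(n, values)
  perfect <- rss <= floor_val
  rss_eff <- max(rss, floor_val)
  R <- qr.R(ls$qr)
  cov_unscaled <- chol2inv(R)
  structure(
    list(order = order,
         coefficients = stats::setNames(beta, paste0("beta", 0:order)),
         time_scaling = st$scaling,
         n = n,
         rss = rss,
         sigma2_hat = rss / n,
         aic = gaussian_aic(rss_eff, n = n, order = order),
         standard_error = if (n > order + 1L) sqrt(rss / (n - order - 1L)) else NA_real_,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         perfect = perfect,
         cov_unscaled = cov_unscaled,
         day_range = c(days[1], days[n])),
    class = "polynomial_fit"
  )
}

#' @export
print.polynomial_fit <- function(x, ...) {
  cat(sprintf("<polynomial_fit> order %d, n=%d, rss=%.4g, AIC=%.2f%s\n",
              x$order, x$n, x$rss, x$aic, if (x$perfect) " (perfect)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Evaluate a polynomial fit at arbitrary days
#'
#' @param fit A `polynomial_fit`.
#' @param days Integer or numeric days on the raw day axis.
#' @return Numeric vector of predicted outcome values.
#' @export
evaluate_fit <- function(fit, days) {
  stopifnot(inherits(fit, "polynomial_fit"))
  u <- (as.numeric(days) - fit$time_scaling[["offset"]]) / fit$time_scaling[["range"]]
  drop(poly_design(u, fit$order) %*% fit$coefficients)
}

#' Candidate polynomial orders for a segment
#'
#' The order must always be lower than the number of points: with 2 values
#' only a 1st order is tried, with 3 values 1st and 2nd, and so on, up to
#' `max_order`. Under `"CONDITIONAL"` rules, subjects whose total measurement
#' count is below `forced_linear_below_n` are allocated a linear model only.
#'
#' @param n_subject Total number of measurements for the subject.
#' @param n_segment Number of measurements in the segment being fitted.
#' @param rules A [rule_config()].
#' @return Increasing integer vector of orders; empty when `n_segment < 2`.
#' @examples
#' candidate_orders(20, 20, rule_config())  # 1 2 3 4
#' candidate_orders(7, 7, rule_config())    # 1 (forced linear)
#' candidate_orders(3, 3, rule_config())    # 1 2
#' @export
candidate_orders <- function(n_subject, n_segment, rules = rule_config()) {
  stopifnot(inherits(rules, "rule_config"))
  if (n_segment < 2L) return(integer(0))
  if (rules$rule_mode == "CONDITIONAL" &&
      n_subject < rules$forced_linear_below_n) {
    return(1L)
  }
  seq_len(min(rules$max_order, n_segment - 1L))
}

#' Fit and select the per-subject trajectory model
#'
#' Runs the full per-subject procedure: the series is partitioned with
#' [segment_for_modelling()], every candidate order (see [candidate_orders()])
#' is fitted to each modellable segment by [fit_polynomial()], and per segment
#' the order with the lowest Gaussian AIC is selected, ties broken toward the
#' lower order (parsimony). Singleton segments are retained unfitted and
#' flagged.
#'
#' @param series A [measurement_series()] that passes [screen_eligibility()].
#' @param rules A [rule_config()].
#' @param check_eligibility Set `FALSE` to skip the eligibility screen (used
#'   internally by the stability resampler, where subsamples may widen gaps
#'   beyond the whole-subject exclusion threshold).
#' @return An object of class `trajectory_model`: `subject_id`,
#'   `n_measurements`, `segments` (each a list with `segment`, `fit` or
#'   `NULL`, `candidate_aics`, `selected_order`), `selected_orders`,
#'   `rule_flags` (subset of `FORCED_LINEAR`, `SEGMENTED`,
#'   `UNMODELLABLE_SEGMENT`) and the `rules` used.
#' @examples
#' s <- measurement_series("a", c(1, 40, 90, 150), c(70, 72, 69, 71))
#' m <- select_trajectory(s)
#' m$selected_orders
#' @export
select_trajectory <- function(series, rules = rule_config(),
                              check_eligibility = TRUE) {
  stopifnot(inherits(series, "measurement_series"),
            inherits(rules, "rule_config"))
  if (check_eligibility) {
    elig <- screen_eligibility(series, rules)
    if (!elig$included) {
      stop("subject '", series$subject_id, "' fails eligibility: ",
           paste(elig$reasons, collapse = ", "), call. = FALSE)
    }
  }
  n_subject <- length(series$days)
  segs <- segment_for_modelling(series, rules)
  flags <- character(0)
  if (length(segs) > 1L) flags <- c(flags, "SEGMENTED")
  if (rules$rule_mode == "CONDITIONAL" &&
      n_subject < rules$forced_linear_below_n) {
    flags <- c(flags, "FORCED_LINEAR")
  }
  fitted_segs <- lapply(segs, function(seg) {
    cands <- candidate_orders(n_subject, length(seg$days), rules)
    if (length(cands) == 0L) {
      return(list(segment = seg, fit = NULL,
                  candidate_aics = stats::setNames(numeric(0), character(0)),
                  selected_order = NA_integer_))
    }
    fits <- lapply(cands, function(p) fit_polynomial(seg, p))
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    names(aics) <- as.character(cands)
    best <- which.min(aics)  # first minimum = lowest order on ties
    list(segment = seg, fit = fits[[best]], candidate_aics = aics,
         selected_order = cands[best])
  })
  if (any(vapply(fitted_segs, function(s) is.null(s$fit), logical(1)))) {
    flags <- c(flags, "UNMODELLABLE_SEGMENT")
  }
  structure(
    list(subject_id = series$subject_id,
         n_measurements = n_subject,
         segments = fitted_segs,
         selected_orders = vapply(fitted_segs, function(s) s$selected_order,
                                  integer(1)),
         rule_flags = flags,
         rules = rules),
    class = "trajectory_model"
  )
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("<trajectory_model> subject %s: n=%d, %d segment(s)%s\n",
              x$subject_id, x$n_measurements, length(x$segments),
              if (length(x$rule_flags))
                paste0(" [", paste(x$rule_flags, collapse = ", "), "]")
              else ""))
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    if (is.null(s$fit)) {
      cat(sprintf("  segment %d: n=%d, non-modellable\n", i,
                  length(s$segment$days)))
    } else {
      cat(sprintf("  segment %d: n=%d, selected order %d (AIC %.2f)\n", i,
                  length(s$segment$days), s$selected_order, s$fit$aic))
    }
  }
  invisible(x)
}

# Order selected for the subject's longest modellable segment (ties toward the
# earlier segment); NA when no segment is modellable. Used as the per-subject
# headline order in stability reports and cohort summaries.
primary_order <- function(model) {
  stopifnot(inherits(model, "trajectory_model"))
  lens <- vapply(model$segments, function(s)
    if (is.null(s$fit)) -1L else length(s$segment$days), integer(1))
  if (all(lens < 0L)) return(NA_integer_)
  model$selected_orders[which.max(lens)]
}
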