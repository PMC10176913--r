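#' Evaluate a trajectory model on the daily grid
#'
#' The selected polynomial of each modelled segment is evaluated at every
#' integer day between that segment's first and last measurement day. Days in
#' unmodelled inter-segment gaps are absent, and the grid never extrapolates
#' beyond the observed endpoints. Pointwise 95% confidence bands for the mean
#' trajectory are attached where the residual degrees of freedom are positive
#' (see [confidence_band()]); otherwise the band is `NA`.
#'
#' @param model A `trajectory_model` from [select_trajectory()].
#' @param level Confidence level for the bands (default 0.95).
#' @return A data frame of class `daily_prediction` with columns
#'   `subject_id`, `day`, `segment`, `predicted`, `ci_low`, `ci_high`,
#'   `implausible` (logical `NA` until [flag_implausible()] is applied). A
#'   subject with no modellable segment yields an empty frame with a warning.
#' @export
predict_daily <- function(model, level = 0.95) {
  stopifnot(inherits(model, "trajectory_model"))
  empty <- data.frame(subject_id = character(0), day = integer(0),
                      segment = integer(0), predicted = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      implausible = logical(0), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_along(model$segments)) {
    s <- model$segments[[i]]
    if (is.null(s$fit)) next
    days <- seq.int(s$segment$days[1], s$segment$days[length(s$segment$days)])
    pred <- evaluate_fit(s$fit, days)
    band <- confidence_band(s$fit, days, level = level)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = model$subject_id, day = as.integer(days), segment = i,
      predicted = pred, ci_low = band$low, ci_high = band$high,
      implausible = NA, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("subject '", model$subject_id,
            "' has no modellable segment; empty prediction", call. = FALSE)
    out <- empty
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("daily_prediction", "data.frame")
  out
}

#' Pointwise confidence band for the mean trajectory
#'
#' Standard OLS confidence interval for the mean response at a day:
#' `fitted +/- t(n - p - 1, 1 - alpha/2) * SE * sqrt(x0' (X'X)^-1 x0)` on the
#' scaled-time basis. This is a band for the fitted trajectory, not a
#' prediction interval for new observations. Undefined (`NA`, not an error)
#' when the fit interpolates (`n = p + 1`, zero residual degrees of freedom).
#'
#' @param fit A `polynomial_fit`.
#' @param day Day (or days) at which to evaluate the band.
#' @param level Confidence level in `(0, 1)`, default 0.95.
#' @return Data frame with columns `low` and `high`, one row per day.
#' @export
confidence_band <- function(fit, day, level = 0.95) {
  stopifnot(inherits(fit, "polynomial_fit"), level > 0, level < 1)
  day <- as.numeric(day)
  df_resid <- fit$n - fit$order - 1L
  if (df_resid < 1L) {
    return(data.frame(low = rep(NA_real_, length(day)),
                      high = rep(NA_real_, length(day))))
  }
  u <- (day - fit$time_scaling[["offset"]]) / fit$time_scaling[["range"]]
  X0 <- poly_design(u, fit$order)
  se_mean <- fit$standard_error * sqrt(rowSums((X0 %*% fit$cov_unscaled) * X0))
  tq <- stats::qt(1 - (1 - level) / 2, df_resid)
  centre <- drop(X0 %*% fit$coefficients)
  data.frame(low = centre - tq * se_mean, high = centre + tq * se_mean)
}

#' Flag implausible daily predictions
#'
#' A daily prediction is implausible when it is negative, or when its absolute
#' deviation from the mean of the subject's observed values exceeds
#' `rel_threshold` (default 30%) of that mean. When the observed mean is not
#' positive the relative rule is skipped with a warning and only negativity
#' applies.
#'
#' @param pred A `daily_prediction` from [predict_daily()].
#' @param series The subject's [measurement_series()] (source of the observed
#'   mean).
#' @param rel_threshold Fraction of the observed mean beyond which a
#'   prediction is flagged (default 0.30).
#' @return `pred` with the `implausible` column filled in.
#' @export
flag_implausible <- function(pred, series, rel_threshold = 0.30) {
  stopifnot(inherits(pred, "daily_prediction"),
            inherits(series, "measurement_series"),
            rel_threshold > 0)
  m <- mean(series$values)
  if (nrow(pred) == 0L) return(pred)
  flag <- pred$predicted < 0
  if (m > 0) {
    flag <- flag | abs(pred$predicted - m) > rel_threshold * m
  } else {
    warning("subject '", series$subject_id,
            "': observed mean <= 0; relative implausibility rule skipped",
            call. = FALSE)
  }
  pred$implausible <- flag
  pred
}

#' Align daily predictions with a daily exposure series
#'
#' Joins a subject's daily predicted outcome with a densely captured exposure
#' (e.g. daily step count from a wearable). `"DAY"` joins on the exact day;
#' `"WEEK"` and `"MONTH"` use consecutive 7- and 30-day blocks anchored at the
#' subject's first predicted day. Within-bin summaries are means of the days
#' available on each side; bins with no overlap between exposure and
#' prediction are dropped.
#'
#' @param pred A `daily_prediction` (one or more subjects).
#' @param exposure Data frame with columns `subject_id`, `day`, `value`; days
#'   unique within subject.
#' @param bin `"DAY"`, `"WEEK"` or `"MONTH"`.
#' @return Data frame with columns `subject_id`, `bin`, `bin_start_day`,
#'   `exposure_mean`, `outcome_pred_mean`, `n_days` (days contributing to both
#'   sides). Exposure rows for subjects absent from `pred` are skipped with a
#'   warning.
#' @export
align_exposure <- function(pred, exposure, bin = c("DAY", "WEEK", "MONTH")) {
  bin <- match.arg(bin)
  stopifnot(is.data.frame(exposure),
            all(c("subject_id", "day", "value") %in% names(exposure)))
  key <- paste(exposure$subject_id, exposure$day)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, day) rows in exposure table", call. = FALSE)
  }
  unknown <- setdiff(unique(exposure$subject_id), unique(pred$subject_id))
  if (length(unknown) > 0) {
    warning("exposure rows skipped for subject(s) without predictions: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  width <- switch(bin, DAY = 1L, WEEK = 7L, MONTH = 30L)
  out <- list()
  for (sid in unique(pred$subject_id)) {
    p <- pred[pred$subject_id == sid, , drop = FALSE]
    e <- exposure[exposure$subject_id == sid, , drop = FALSE]
    if (nrow(p) == 0L || nrow(e) == 0L) next
    anchor <- min(p$day)
    pb <- (p$day - anchor) %/% width
    eb <- (e$day - anchor) %/% width
    for (b in sort(intersect(unique(pb), unique(eb)))) {
      pd <- p$day[pb == b]
      ed <- e$day[eb == b]
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, bin = b, bin_start_day = anchor + b * width,
        exposure_mean = mean(e$value[eb == b]),
        outcome_pred_mean = mean(p$predicted[pb == b]),
        n_days = length(intersect(pd, ed)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(subject_id = character(0), bin = integer(0),
                      bin_start_day = integer(0), exposure_mean = numeric(0),
                      outcome_pred_mean = numeric(0), n_days = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
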