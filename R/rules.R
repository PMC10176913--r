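#' Eligibility and sparsity rules for trajectory modelling
#'
#' Bundles the thresholds that govern which subjects are modellable and how
#' sparse series are constrained. Defaults reproduce the reference analysis:
#' subjects need at least 2 measurements and no gap over 1 year (365 days);
#' under `rule_mode = "CONDITIONAL"` subjects with fewer than 8 measurements
#' are forced to a linear model, and subjects with fewer than 15 measurements
#' are segmented at any gap of 6 months (183 days) or more so that models are
#' only generated between consecutive measurements within 6 months.
#'
#' @param max_intra_subject_gap_days Gaps longer than this exclude the whole
#'   subject (days; default 365).
#' @param min_measurements Minimum number of measurements for eligibility
#'   (default 2; a trend needs two points).
#' @param forced_linear_below_n Subjects with fewer measurements than this are
#'   restricted to a 1st-order model (default 8).
#' @param segmentation_below_n Subjects with fewer measurements than this are
#'   split at long gaps (default 15).
#' @param segmentation_gap_days Gap at or above which a sparse subject's series
#'   is split (days; default 183).
#' @param max_order Highest polynomial order ever considered (default 4,
#'   guarding against overfitting).
#' @param rule_mode `"CONDITIONAL"` applies the forced-linear and segmentation
#'   rules; `"UNRESTRICTED"` considers orders `1:max_order` (capped at
#'   n - 1) for everyone and never segments.
#'
#' @return An object of class `rule_config`.
#' @examples
#' rule_config()
#' rule_config(rule_mode = "UNRESTRICTED")
#' @export
rule_config <- function(max_intra_subject_gap_days = 365L,
                        min_measurements = 2L,
                        forced_linear_below_n = 8L,
                        segmentation_below_n = 15L,
                        segmentation_gap_days = 183L,
                        max_order = 4L,
                        rule_mode = c("CONDITIONAL", "UNRESTRICTED")) {
  rule_mode <- match.arg(rule_mode)
  cfg <- list(
    max_intra_subject_gap_days = as.integer(max_intra_subject_gap_days),
    min_measurements = as.integer(min_measurements),
    forced_linear_below_n = as.integer(forced_linear_below_n),
    segmentation_below_n = as.integer(segmentation_below_n),
    segmentation_gap_days = as.integer(segmentation_gap_days),
    max_order = as.integer(max_order),
    rule_mode = rule_mode
  )
  if (cfg$max_order < 1L) stop("max_order must be >= 1", call. = FALSE)
  if (cfg$forced_linear_below_n > cfg$segmentation_below_n) {
    stop("forced_linear_below_n must not exceed segmentation_below_n",
         call. = FALSE)
  }
  if (cfg$max_intra_subject_gap_days <= 0L || cfg$segmentation_gap_days <= 0L) {
    stop("day thresholds must be positive", call. = FALSE)
  }
  if (cfg$min_measurements < 1L) stop("min_measurements must be >= 1", call. = FALSE)
  structure(cfg, class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config>", x$rule_mode, "\n")
  cat(sprintf("  eligibility: n >= %d, max gap <= %d d\n",
              x$min_measurements, x$max_intra_subject_gap_days))
  cat(sprintf("  forced linear below n = %d; segmentation below n = %d at gaps >= %d d\n",
              x$forced_linear_below_n, x$segmentation_below_n,
              x$segmentation_gap_days))
  cat(sprintf("  candidate orders: 1..%d\n", x$max_order))
  invisible(x)
}

#' Screen a subject for eligibility
#'
#' A subject is included when it has at least `min_measurements` measurements
#' and no gap between consecutive measurements exceeding
#' `max_intra_subject_gap_days`. A gap over the limit excludes the whole
#' subject; the series is never split at that stage.
#'
#' @param series A [measurement_series()].
#' @param rules A [rule_config()].
#' @return An object of class `eligibility_result`: list with `subject_id`,
#'   `included`, `reasons` (character vector, subset of
#'   `"TOO_FEW_MEASUREMENTS"`, `"GAP_OVER_ONE_YEAR"`), `n_measurements`,
#'   `max_gap_days`.
#' @examples
#' screen_eligibility(measurement_series("a", c(1, 401), c(60, 65)), rule_config())
#' @export
screen_eligibility <- function(series, rules = rule_config()) {
  stopifnot(inherits(series, "measurement_series"),
            inherits(rules, "rule_config"))
  n <- length(series$days)
  gap <- max_gap_days(series)
  reasons <- character(0)
  if (n < rules$min_measurements) reasons <- c(reasons, "TOO_FEW_MEASUREMENTS")
  if (gap > rules$max_intra_subject_gap_days) {
    reasons <- c(reasons, "GAP_OVER_ONE_YEAR")
  }
  structure(
    list(subject_id = series$subject_id,
         included = length(reasons) == 0L,
         reasons = reasons,
         n_measurements = n,
         max_gap_days = gap),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("<eligibility_result> subject %s: %s (n=%d, max gap=%d d)%s\n",
              x$subject_id, if (x$included) "included" else "excluded",
              x$n_measurements, x$max_gap_days,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

new_segment <- function(series, start, end) {
  idx <- start:end
  structure(
    list(subject_id = series$subject_id,
         start_index = start,
         end_index = end,
         days = series$days[idx],
         values = series$values[idx],
         modellable = length(idx) >= 2L),
    class = "trajectory_segment"
  )
}

#' @export
print.trajectory_segment <- function(x, ...) {
  cat(sprintf("<segment> subject %s [%d:%d], days %d-%d (n=%d%s)\n",
              x$subject_id, x$start_index, x$end_index,
              x$days[1], x$days[length(x$days)], length(x$days),
              if (x$modellable) "" else ", non-modellable"))
  invisible(x)
}

#' Partition a sparse series into modellable segments
#'
#' Subjects with at least `segmentation_below_n` measurements (or any subject
#' under `"UNRESTRICTED"` rules) are returned as one segment spanning the full
#' series. Sparser subjects are split at every consecutive gap of
#' `segmentation_gap_days` or more, so that within every returned segment all
#' consecutive gaps are strictly below the threshold. Singleton segments are
#' retained but flagged non-modellable. Segments are non-overlapping, ordered,
#' and their union reproduces the input series exactly.
#'
#' @inheritParams screen_eligibility
#' @return List of `trajectory_segment` objects.
#' @examples
#' s <- measurement_series("a", c(1, 20, 40, 300, 320), c(70, 71, 69, 66, 67))
#' segment_for_modelling(s, rule_config())   # split at the 260-day gap
#' @export
segment_for_modelling <- function(series, rules = rule_config()) {
  stopifnot(inherits(series, "measurement_series"),
            inherits(rules, "rule_config"))
  n <- length(series$days)
  if (rules$rule_mode == "UNRESTRICTED" || n >= rules$segmentation_below_n ||
      n == 1L) {
    return(list(new_segment(series, 1L, n)))
  }
  gaps <- diff(series$days)
  cut_after <- which(gaps >= rules$segmentation_gap_days)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  mapply(function(s, e) new_segment(series, s, e), starts, ends,
         SIMPLIFY = FALSE)
}
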