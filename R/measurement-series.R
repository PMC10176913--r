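#' One subject's repeated outcome measurements
#'
#' Container for a single individual's longitudinal series of a continuous
#' clinical outcome (e.g. FEV1 % predicted, BMI) on an integer day axis where
#' day 1 is the day of the first measurement.
#'
#' @param subject_id Identifier for the subject (coerced to character).
#' @param days Integer day indices, strictly increasing. By convention the
#'   first measurement falls on day 1, but any strictly increasing integer
#'   sequence is accepted.
#' @param values Numeric outcome measurements, same length as `days`, all
#'   finite.
#' @param outcome_label Free-text label for the outcome and its units.
#'
#' @return An object of class `measurement_series`: a list with elements
#'   `subject_id`, `days`, `values` and `outcome_label`.
#' @examples
#' s <- measurement_series("s1", days = c(1, 30, 62), values = c(71.2, 69.8, 70.5))
#' s
#' @export
measurement_series <- function(subject_id, days, values,
                               outcome_label = "outcome") {
  subject_id <- as.character(subject_id)[1]
  if (length(days) != length(values)) {
    stop("subject '", subject_id, "': days and values must have equal length",
         call. = FALSE)
  }
  if (length(days) < 1L) {
    stop("subject '", subject_id, "': at least one measurement is required",
         call. = FALSE)
  }
  days <- as.numeric(days)
  values <- as.numeric(values)
  if (anyNA(days) || any(!is.finite(days)) || any(days != round(days))) {
    stop("subject '", subject_id, "': days must be finite integers",
         call. = FALSE)
  }
  if (length(days) > 1L && any(diff(days) <= 0)) {
    stop("subject '", subject_id,
         "': day sequence must be strictly increasing (sort and deduplicate first)",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("subject '", subject_id, "': all outcome values must be finite",
         call. = FALSE)
  }
  structure(
    list(subject_id = subject_id,
         days = as.integer(days),
         values = values,
         outcome_label = as.character(outcome_label)[1]),
    class = "measurement_series"
  )
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("<measurement_series> subject %s: %d measurements of %s over days %d-%d\n",
              x$subject_id, length(x$days), x$outcome_label,
              min(x$days), max(x$days)))
  invisible(x)
}

#' @export
as.data.frame.measurement_series <- function(x, ...) {
  data.frame(subject_id = x$subject_id, day = x$days, value = x$values,
             stringsAsFactors = FALSE)
}

#' @export
length.measurement_series <- function(x) length(x$days)

#' Maximum gap, in days, between consecutive measurements
#'
#' @param series A [measurement_series()].
#' @return Integer; 0 when the series has fewer than 2 measurements.
#' @export
max_gap_days <- function(series) {
  stopifnot(inherits(series, "measurement_series"))
  if (length(series$days) < 2L) return(0L)
  as.integer(max(diff(series$days)))
}

#' Read long-format measurement tables
#'
#' Reads a CSV with columns `subject_id`, `day` (integer) or `date`
#' (ISO-8601), and `value`, and returns one [measurement_series()] per
#' subject. When a `date` column is supplied it is converted per subject to
#' day offsets with the first measurement on day 1. Rows are sorted by day
#' within subject; duplicate (subject, day) rows and unparseable values are
#' hard errors that list the offending rows.
#'
#' @param path Path to the CSV file.
#' @param outcome_label Label attached to every series.
#' @return Named list of `measurement_series`, in order of first appearance.
#' @export
read_measurements <- function(path, outcome_label = "outcome") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- names(raw)
  if (!"subject_id" %in% cols || !"value" %in% cols ||
      !any(c("day", "date") %in% cols)) {
    stop("expected columns subject_id, day|date, value; found: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value) | !is.finite(value))
  if (length(bad) > 0) {
    stop("unparseable or non-finite values at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if ("day" %in% cols) {
    day <- suppressWarnings(as.numeric(raw$day))
    bad <- which(is.na(day) | day != round(day))
    if (length(bad) > 0) {
      stop("unparseable day values at data row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  } else {
    dt <- as.Date(raw$date, format = "%Y-%m-%d")
    bad <- which(is.na(dt))
    if (length(bad) > 0) {
      stop("unparseable ISO-8601 dates at data row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    day <- rep(NA_real_, nrow(raw))
    for (sid in unique(raw$subject_id)) {
      i <- raw$subject_id == sid
      day[i] <- as.numeric(dt[i] - min(dt[i])) + 1
    }
  }
  key <- paste(raw$subject_id, day, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (subject_id, day) rows: ",
         paste(utils::head(dups, 10), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (sid in unique(as.character(raw$subject_id))) {
    i <- which(as.character(raw$subject_id) == sid)
    o <- order(day[i])
    out[[sid]] <- measurement_series(sid, day[i][o], value[i][o],
                                     outcome_label = outcome_label)
  }
  out
}

#' Write a cohort back to long-format CSV
#'
#' Inverse of [read_measurements()]: writing then re-reading reproduces the
#' in-memory series exactly.
#'
#' @param cohort A list of [measurement_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(cohort, path) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  df <- do.call(rbind, lapply(cohort, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
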