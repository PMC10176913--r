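#' Configuration for a full pipeline run
#'
#' @param input Path to a long-format measurement CSV (see
#'   [read_measurements()]), or an in-memory named list of
#'   [measurement_series()].
#' @param output_dir Directory for artefact files (created if absent).
#' @param rules A [rule_config()].
#' @param exposure Optional path to a daily exposure CSV (`subject_id`, `day`,
#'   `value`) or an equivalent data frame.
#' @param alignment_bin `"DAY"`, `"WEEK"` or `"MONTH"`; alignment is skipped
#'   when `exposure` is `NULL`.
#' @param run_stability,run_pairwise Evaluation toggles.
#' @param stability_fraction,stability_iterations Stability resampling
#'   settings (defaults 0.8 and 100).
#' @param pairwise_max_gap_days Pairing window for [pairwise_change()]
#'   (default 183).
#' @param investigation_threshold Residual exceedance threshold, outcome
#'   units (default 20).
#' @param rel_threshold Implausibility threshold as a fraction of the
#'   observed mean (default 0.30).
#' @param seed Integer seed for all stochastic steps.
#' @param force Overwrite existing artefact files (default `FALSE`).
#' @param verbose Print progress messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, output_dir, rules = rule_config(),
                       exposure = NULL, alignment_bin = "WEEK",
                       run_stability = TRUE, run_pairwise = TRUE,
                       stability_fraction = 0.8, stability_iterations = 100L,
                       pairwise_max_gap_days = 183L,
                       investigation_threshold = 20,
                       rel_threshold = 0.30,
                       seed = 1L, force = FALSE, verbose = TRUE) {
  if (is.character(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  if (is.character(exposure) && !file.exists(exposure)) {
    stop("exposure file not found: ", exposure, call. = FALSE)
  }
  structure(
    list(input = input, output_dir = output_dir, rules = rules,
         exposure = exposure, alignment_bin = alignment_bin,
         run_stability = run_stability, run_pairwise = run_pairwise,
         stability_fraction = stability_fraction,
         stability_iterations = as.integer(stability_iterations),
         pairwise_max_gap_days = as.integer(pairwise_max_gap_days),
         investigation_threshold = investigation_threshold,
         rel_threshold = rel_threshold,
         seed = as.integer(seed), force = isTRUE(force),
         verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Flatten a set of trajectory models to a model-dump table
#'
#' One row per (subject, segment): measurement counts, selected order,
#' coefficients on the scaled basis, time scaling, fit statistics, candidate
#' AICs and rule flags.
#'
#' @param models List of `trajectory_model` objects.
#' @param max_order Number of coefficient / AIC columns to allocate.
#' @return A data frame.
#' @export
model_dump <- function(models, max_order = 4L) {
  if (inherits(models, "trajectory_model")) models <- list(models)
  rows <- list()
  for (m in models) {
    for (i in seq_along(m$segments)) {
      s <- m$segments[[i]]
      coefs <- rep(NA_real_, max_order + 1L)
      aics <- rep(NA_real_, max_order)
      row <- data.frame(subject_id = m$subject_id, segment = i,
                        n_subject = m$n_measurements,
                        n_segment = length(s$segment$days),
                        selected_order = s$selected_order,
                        stringsAsFactors = FALSE)
      if (!is.null(s$fit)) {
        coefs[seq_len(s$fit$order + 1L)] <- unname(s$fit$coefficients)
        aics[as.integer(names(s$candidate_aics))] <- unname(s$candidate_aics)
        row$time_offset <- s$fit$time_scaling[["offset"]]
        row$time_range <- s$fit$time_scaling[["range"]]
        row$rss <- s$fit$rss
        row$standard_error <- s$fit$standard_error
        row$r_squared <- s$fit$r_squared
      } else {
        row$time_offset <- NA_real_; row$time_range <- NA_real_
        row$rss <- NA_real_; row$standard_error <- NA_real_
        row$r_squared <- NA_real_
      }
      for (j in 0:max_order) row[[paste0("coef_", j)]] <- coefs[j + 1L]
      for (p in 1:max_order) row[[paste0("aic_", p)]] <- aics[p]
      row$flags <- paste(m$rule_flags, collapse = ";")
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full trajectory pipeline and write artefact files
#'
#' Executes screen -> segment -> fit/select -> daily prediction ->
#' implausibility flagging -> evaluation (residuals, pairwise change,
#' stability) -> optional exposure alignment, and writes one CSV per stage
#' plus a YAML run log capturing the effective configuration, seed and
#' cohort summary, so a run is reproducible from its log alone.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`eligibility`,
#'   `models`, `predictions`, `residuals`, `pairwise`, `stability`,
#'   `aligned`) and `files`, the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  cohort <- if (is.character(config$input)) {
    read_measurements(config$input)
  } else config$input
  stopifnot(is.list(cohort), length(cohort) > 0)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$output_dir,
                     c(eligibility = "eligibility.csv",
                       models = "model_dump.csv",
                       predictions = "daily_predictions.csv",
                       residuals = "residuals.csv",
                       pairwise = "pairwise_changes.csv",
                       stability = "stability.csv",
                       aligned = "aligned_exposure.csv",
                       log = "run_log.yaml"))
  names(paths) <- c("eligibility", "models", "predictions", "residuals",
                    "pairwise", "stability", "aligned", "log")
  if (!config$force && any(file.exists(paths))) {
    stop("output files already present in ", config$output_dir,
         "; use force = TRUE to overwrite", call. = FALSE)
  }

  elig <- lapply(cohort, screen_eligibility, rules = config$rules)
  elig_df <- data.frame(
    subject_id = vapply(elig, `[[`, character(1), "subject_id"),
    included = vapply(elig, `[[`, logical(1), "included"),
    n_measurements = vapply(elig, `[[`, integer(1), "n_measurements"),
    max_gap_days = vapply(elig, `[[`, integer(1), "max_gap_days"),
    reasons = vapply(elig, function(e) paste(e$reasons, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(elig_df, paths[["eligibility"]], row.names = FALSE)
  included <- cohort[elig_df$included]
  say("eligibility: %d of %d subjects included", length(included),
      length(cohort))
  if (length(included) == 0L) {
    stop("no eligible subjects in cohort", call. = FALSE)
  }

  models <- lapply(included, select_trajectory, rules = config$rules)
  utils::write.csv(model_dump(models, config$rules$max_order),
                   paths[["models"]], row.names = FALSE)

  preds <- lapply(names(models), function(sid) {
    p <- suppressWarnings(predict_daily(models[[sid]]))
    flag_implausible(p, included[[sid]], config$rel_threshold)
  })
  pred_all <- do.call(rbind, preds)
  utils::write.csv(pred_all, paths[["predictions"]], row.names = FALSE)
  say("predicted %d subject-days", nrow(pred_all))

  res <- residual_summary(models, config$investigation_threshold)
  utils::write.csv(res$observations, paths[["residuals"]], row.names = FALSE)

  pairwise <- NULL
  if (config$run_pairwise) {
    pairwise <- do.call(rbind, lapply(names(models), function(sid)
      pairwise_change(models[[sid]], config$pairwise_max_gap_days)))
    utils::write.csv(pairwise, paths[["pairwise"]], row.names = FALSE)
  }

  stability <- NULL
  if (config$run_stability) {
    stability <- stability_cohort(included, config$rules,
                                  fraction = config$stability_fraction,
                                  iterations = config$stability_iterations,
                                  seed = config$seed)
    utils::write.csv(stability$per_subject, paths[["stability"]],
                     row.names = FALSE)
  }

  aligned <- NULL
  if (!is.null(config$exposure)) {
    exposure <- if (is.character(config$exposure)) {
      utils::read.csv(config$exposure, stringsAsFactors = FALSE)
    } else config$exposure
    aligned <- align_exposure(pred_all, exposure, config$alignment_bin)
    utils::write.csv(aligned, paths[["aligned"]], row.names = FALSE)
  }

  log <- list(
    configuration = list(
      input = if (is.character(config$input)) config$input else "<in-memory>",
      output_dir = config$output_dir,
      rules = unclass(config$rules),
      alignment_bin = config$alignment_bin,
      stability = list(run = config$run_stability,
                       fraction = config$stability_fraction,
                       iterations = config$stability_iterations),
      pairwise = list(run = config$run_pairwise,
                      max_gap_days = config$pairwise_max_gap_days),
      investigation_threshold = config$investigation_threshold,
      rel_threshold = config$rel_threshold,
      seed = config$seed),
    cohort = list(n_subjects = length(cohort),
                  n_included = length(included),
                  n_predicted_days = nrow(pred_all)),
    selected_orders = as.list(table(unlist(lapply(models, primary_order)))))
  yaml::write_yaml(log, paths[["log"]])
  say("artefacts written to %s", config$output_dir)

  invisible(list(eligibility = elig_df, models = models,
                 predictions = pred_all, residuals = res,
                 pairwise = pairwise, stability = stability,
                 aligned = aligned, files = paths))
}
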