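#' Flatten sessions into a trial-log table
#'
#' One row per trial: participant, test, trial index, movement direction,
#' start and stimulus positions (mm), stimulus source (psi/far/near),
#' response, and the post-update engine estimates.
#'
#' @param x A `psi_session`, list of sessions, `psi_cohort`, or an
#'   already-flat trial-log data frame (returned unchanged).
#' @return A trial-log data frame.
#' @export
trial_log <- function(x) {
  cols <- c("participant_id", "test_id", "trial", "direction", "start_mm",
            "stimulus_mm", "stimulus_source", "response", "alpha_hat_mm",
            "beta_hat_mm")
  if (is.data.frame(x)) {
    if (!all(cols %in% names(x)))
      stop_psiprop("trial log must have columns ", paste(cols, collapse = ", "))
    return(x[cols])
  }
  if (inherits(x, "psi_cohort")) x <- x$sessions
  if (inherits(x, "psi_session")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "psi_session")))
    stop_psiprop("`x` must be psi_session(s), a psi_cohort, or a trial-log data frame")
  do.call(rbind, lapply(x, function(s) {
    cbind(data.frame(participant_id = s$participant_id, test_id = s$test_id,
                     stringsAsFactors = FALSE),
          s$trials)
  }))[, cols]
}

#' Write / read the trial-log CSV
#'
#' @param x Sessions in any form accepted by [trial_log()].
#' @param path Output CSV path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns the trial-log data frame.
#' @export
write_trial_log <- function(x, path) {
  utils::write.csv(trial_log(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_log(df)
}

#' Write / read the session-summary CSV
#'
#' One row per participant, test and checkpoint with the recorded engine
#' estimates.
#'
#' @param x Sessions in any form accepted by [session_summary()].
#' @param path Output CSV path.
#' @export
write_session_summary <- function(x, path) {
  utils::write.csv(session_summary(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_summary
#' @export
read_session_summary <- function(path) {
  session_summary(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write the ground-truth CSV of a simulated cohort
#'
#' @param cohort A `psi_cohort`.
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(cohort, path) {
  if (!inherits(cohort, "psi_cohort")) stop_psiprop("`cohort` must be a psi_cohort")
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}

summary_to_list <- function(s) {
  list(parameter = s$parameter, mean = s$mean, hdi_low = s$hdi_low,
       hdi_high = s$hdi_high, rope_low = s$rope_low, rope_high = s$rope_high,
       rope_fraction = s$rope_fraction)
}

#' Serialise an agreement report to JSON
#'
#' All posterior summaries, HDIs, ROPE fractions, limits of agreement, ICCs
#' and MCMC diagnostics, without the raw draws.
#'
#' @param report An [agreement_report()].
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
agreement_report_json <- function(report, path = NULL) {
  if (!inherits(report, "agreement_report"))
    stop_psiprop("`report` must be an agreement_report")
  payload <- list(
    n_participants = report$n_participants,
    checkpoints = report$checkpoints,
    mcmc = unclass(report$mcmc),
    results = lapply(report$results, function(res) {
      list(checkpoint = res$checkpoint, parameter = res$parameter,
           loa_low = unname(res$loa[1]), loa_high = unname(res$loa[2]),
           mean_bias = summary_to_list(res$mean_bias$mu),
           bias_regression = list(
             intercept = summary_to_list(res$bias_regression$intercept),
             slope = summary_to_list(res$bias_regression$slope)),
           retest_regression = list(
             intercept = summary_to_list(res$retest_regression$intercept),
             slope = summary_to_list(res$retest_regression$slope)),
           icc = list(icc = res$icc$icc, ci_low = res$icc$ci_low,
                      ci_high = res$icc$ci_high,
                      degenerate = res$icc$degenerate),
           good_agreement = res$good_agreement)
    }),
    direction_contrast = if (!is.null(report$direction))
      summary_to_list(report$direction$contrast))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Replay a trial log through the Psi engine
#'
#' Re-runs the sequential Bayes updates on the logged (stimulus, response)
#' pairs of each session and returns the recomputed estimate trajectory.
#' With the grids that produced the log, the recomputed estimates match the
#' logged ones to numerical precision; mismatches indicate a different grid
#' or a corrupted log.
#'
#' @param trials A trial-log data frame (see [trial_log()]).
#' @param grid A [parameter_grid()].
#' @param stimuli A [stimulus_grid()].
#' @return The trial log with recomputed columns `alpha_replay_mm`,
#'   `beta_replay_mm` and the absolute deviations from the logged estimates.
#' @export
replay_trial_log <- function(trials, grid = parameter_grid(),
                             stimuli = stimulus_grid()) {
  trials <- trial_log(trials)
  bad <- which(!trials$response %in% c("left", "right") |
                 !is.finite(trials$stimulus_mm))
  if (length(bad) > 0L)
    stop_psiprop("malformed trial-log rows: ", paste(bad, collapse = ", "))
  tables <- likelihood_tables(grid, stimuli)
  out <- trials
  out$alpha_replay_mm <- NA_real_
  out$beta_replay_mm <- NA_real_
  key <- interaction(trials$participant_id, trials$test_id, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    idx <- idx[order(trials$trial[idx])]
    post <- init_posterior(grid)
    for (i in idx) {
      post <- update_posterior(post, tables, trials$stimulus_mm[i],
                               trials$response[i])
      est <- marginal_estimates(post)
      out$alpha_replay_mm[i] <- est$alpha_hat
      out$beta_replay_mm[i] <- est$beta_hat
    }
  }
  out$alpha_abs_dev <- abs(out$alpha_replay_mm - out$alpha_hat_mm)
  out$beta_abs_dev <- abs(out$beta_replay_mm - out$beta_hat_mm)
  out
}
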