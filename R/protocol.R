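#' Protocol configuration for one 2AFC session
#'
#' Defaults reproduce the standing proprioception protocol: 75 trials on the
#' 21-location stimulus grid, start positions drawn around +/-100 mm with a
#' 5 mm SD, far engagement stimuli (+/-90, +/-100 mm) once per complete
#' 10-trial block and near stimuli (current PSE estimate +/-10/20/30 mm,
#' snapped to the grid) once per complete 5-trial block, none within the
#' first five trials, and estimate checkpoints after trials 25, 50 and 75.
#' Belt speeds are stored as metadata only; they do not enter any
#' computation.
#'
#' @param n_trials Number of trials per session.
#' @param stimuli A [stimulus_grid()].
#' @param start_center Magnitude (mm) of the two start-position distribution
#'   centres (+center for backward trials, -center for forward trials).
#' @param start_sd SD (mm) of the start-position distributions.
#' @param far_values Far preselected stimulus set (mm).
#' @param near_offsets Offsets (mm) added to the current PSE estimate for
#'   near preselected stimuli.
#' @param far_period,near_period Block lengths: one far (near) insertion per
#'   complete block of this many trials.
#' @param preselect_exclusion_first_n No preselected stimuli within the first
#'   this-many trials.
#' @param checkpoints Trial indices at which estimates are recorded. Defaults
#'   to 25/50/75 clipped to `n_trials` (always including the final trial).
#' @param resample_cap Maximum rejection-sampling draws for a start position.
#' @param start_speed_range,stimulus_speed_range Belt speeds (mm/s), metadata.
#' @return An object of class `"protocol_config"`.
#' @export
protocol_config <- function(n_trials = 75,
                            stimuli = stimulus_grid(),
                            start_center = 100,
                            start_sd = 5,
                            far_values = c(-100, -90, 90, 100),
                            near_offsets = c(-30, -20, -10, 10, 20, 30),
                            far_period = 10,
                            near_period = 5,
                            preselect_exclusion_first_n = 5,
                            checkpoints = NULL,
                            resample_cap = 1000,
                            start_speed_range = c(40, 50),
                            stimulus_speed_range = c(10, 30)) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop_psiprop("`n_trials` must be >= 1")
  if (!inherits(stimuli, "stimulus_grid")) stimuli <- stimulus_grid(stimuli)
  if (start_sd <= 0) stop_psiprop("`start_sd` must be positive")
  if (far_period < 1 || near_period < 1) stop_psiprop("periods must be >= 1")
  if (is.null(checkpoints)) {
    checkpoints <- unique(c(c(25L, 50L, 75L)[c(25L, 50L, 75L) <= n_trials], n_trials))
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 1L) || any(checkpoints > n_trials))
    stop_psiprop("`checkpoints` must lie within 1..n_trials")
  structure(list(n_trials = n_trials, stimuli = stimuli,
                 start_center = start_center, start_sd = start_sd,
                 far_values = far_values, near_offsets = near_offsets,
                 far_period = as.integer(far_period),
                 near_period = as.integer(near_period),
                 preselect_exclusion_first_n = as.integer(preselect_exclusion_first_n),
                 checkpoints = checkpoints,
                 resample_cap = as.integer(resample_cap),
                 start_speed_range = start_speed_range,
                 stimulus_speed_range = stimulus_speed_range),
            class = "protocol_config")
}

#' Pseudorandomised movement-direction schedule
#'
#' Assigns each trial a start label: `"front"` (test foot starts in front of
#' the stimulus, so it moves backward to reach it) or `"behind"` (moves
#' forward). For 75 trials the split is exactly 38 front / 37 behind; in
#' general `ceiling(n/2)` front and `floor(n/2)` behind, in random order.
#' Balancing the two directions washes out any response bias tied to the
#' movement direction.
#'
#' @param n_trials Number of trials.
#' @return Character vector of `"front"` / `"behind"` labels.
#' @export
make_direction_schedule <- function(n_trials) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop_psiprop("`n_trials` must be >= 1")
  labels <- c(rep("front", ceiling(n_trials / 2)),
              rep("behind", floor(n_trials / 2)))
  sample(labels)
}

#' Movement direction implied by a start label
#'
#' Starting in front of the stimulus means the belt moves the foot backward
#' to reach it; starting behind means forward.
#'
#' @param start_label `"front"` or `"behind"`.
#' @return `"backward"` or `"forward"`.
#' @export
direction_from_start <- function(start_label) {
  ifelse(start_label == "front", "backward", "forward")
}

#' Sample a trial's start position
#'
#' Forward trials draw from Normal(-start_center, start_sd) until the draw is
#' below the stimulus; backward trials from Normal(+start_center, start_sd)
#' until above it. Rejection guarantees the labelled movement direction is
#' geometrically valid. The acceptance probability is at least one half for
#' every grid stimulus, so the cap only trips on misconfiguration.
#'
#' @param direction `"forward"` or `"backward"`.
#' @param stimulus Target stimulus (mm).
#' @param config A [protocol_config()].
#' @return Start position (mm).
#' @export
sample_start_position <- function(direction, stimulus, config = protocol_config()) {
  direction <- match.arg(direction, c("forward", "backward"))
  center <- if (direction == "forward") -config$start_center else config$start_center
  for (i in seq_len(config$resample_cap)) {
    x <- stats::rnorm(1, center, config$start_sd)
    ok <- if (direction == "forward") x < stimulus else x > stimulus
    if (ok) return(x)
  }
  stop_psiprop("could not sample a valid start position within resample_cap draws; ",
               "check start distribution vs stimulus ", stimulus)
}

#' Assign preselected (engagement) trials
#'
#' One far stimulus is placed uniformly at random in each complete block of
#' `far_period` trials, and one near stimulus in each complete block of
#' `near_period` trials; no insertion within the first
#' `preselect_exclusion_first_n` trials. Far placement takes precedence: a
#' near draw colliding with a far trial is re-placed within its own block
#' (dropped if the block has no free slot). With the 75-trial defaults this
#' yields exactly 7 far and 14 near trials.
#'
#' @param n_trials Number of trials.
#' @param config A [protocol_config()].
#' @return Character vector of length `n_trials` with values `"psi"`,
#'   `"far"`, `"near"`.
#' @export
assign_preselected_trials <- function(n_trials, config = protocol_config()) {
  n_trials <- as.integer(n_trials)
  source <- rep("psi", n_trials)
  excluded <- seq_len(min(config$preselect_exclusion_first_n, n_trials))
  place <- function(period, kind) {
    starts <- seq(1L, n_trials, by = period)
    for (s in starts) {
      block <- s:(s + period - 1L)
      if (max(block) > n_trials) next  # incomplete trailing block
      cand <- setdiff(block, excluded)
      cand <- cand[source[cand] == "psi"]
      if (length(cand) == 0L) next
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      source[pick] <<- kind
    }
  }
  place(config$far_period, "far")
  place(config$near_period, "near")
  source
}

#' Draw a preselected stimulus
#'
#' Far stimuli are drawn uniformly from the far set (+/-90, +/-100 mm). Near
#' stimuli add a uniform draw from the near offsets (+/-10/20/30 mm) to the
#' current PSE estimate and snap to the nearest grid location (which also
#' clips to the grid range).
#'
#' @param kind `"far"` or `"near"`.
#' @param current_pse Current engine PSE estimate (mm); used for near trials.
#' @param config A [protocol_config()].
#' @return A stimulus on the grid (mm).
#' @export
preselected_stimulus <- function(kind, current_pse = 0, config = protocol_config()) {
  kind <- match.arg(kind, c("far", "near"))
  grid <- unclass(config$stimuli)
  if (kind == "far") {
    v <- config$far_values
    return(v[sample.int(length(v), 1L)])
  }
  off <- config$near_offsets
  target <- current_pse + off[sample.int(length(off), 1L)]
  grid[which.min(abs(grid - target))]
}

#' Baseline marker-offset correction
#'
#' With heels aligned, any residual left-right difference of the ankle
#' markers along the walking axis is recorded and rounded to the nearest
#' millimetre (half away from zero); stimulus positions and PSE estimates
#' are then reported relative to this offset.
#'
#' @param left_marker_y,right_marker_y Marker positions (mm) along the
#'   walking axis.
#' @return Integer offset in mm.
#' @examples
#' baseline_offset(1003.4, 1001.2)  # 2
#' @export
baseline_offset <- function(left_marker_y, right_marker_y) {
  if (!is.finite(left_marker_y) || !is.finite(right_marker_y))
    stop_psiprop("marker positions must be finite")
  d <- left_marker_y - right_marker_y
  as.integer(sign(d) * floor(abs(d) + 0.5))
}

#' Run one adaptive 2AFC session
#'
#' Executes the full per-trial loop: direction scheduling, stimulus choice
#' (Psi selection unless the trial is a preselected far/near insertion),
#' start-position sampling, querying the responder, Bayes update of the
#' joint posterior, and bookkeeping of running estimates and checkpoints.
#' The posterior is updated on every trial's response, including preselected
#' trials.
#'
#' @param responder Function `(stimulus, direction) -> "left" | "right"`;
#'   see [make_responder()] for simulated observers.
#' @param config A [protocol_config()].
#' @param grid A [parameter_grid()] for the engine.
#' @param seed Optional integer seed; if supplied the session is exactly
#'   reproducible.
#' @param participant_id,test_id Identifiers recorded in the logs.
#' @param baseline_offset_mm Integer baseline correction (mm), recorded as
#'   session metadata.
#' @param tables Optional precomputed [likelihood_tables()] (shared across
#'   sessions for speed); must match `grid` and `config$stimuli`.
#' @return An object of class `"psi_session"`: trial log (`$trials`),
#'   checkpoint estimates (`$checkpoints`), the final posterior and metadata.
#' @examples
#' obs <- observer_spec(12, 18)
#' s <- run_session(make_responder(obs), protocol_config(), seed = 1)
#' s
#' @export
run_session <- function(responder, config = protocol_config(),
                        grid = parameter_grid(), seed = NULL,
                        participant_id = "P01", test_id = 1L,
                        baseline_offset_mm = 0L, tables = NULL) {
  if (!is.function(responder)) stop_psiprop("`responder` must be a function")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tables <- tables %||% likelihood_tables(grid, config$stimuli)
  if (!identical(dim(tables$left)[1:2],
                 c(length(grid$alpha_values), length(grid$beta_values))))
    stop_psiprop("`tables` do not match `grid`")
  post <- init_posterior(grid)
  est <- marginal_means(post)
  n <- config$n_trials
  start_labels <- make_direction_schedule(n)
  sources <- assign_preselected_trials(n, config)

  trials <- data.frame(trial = seq_len(n), direction = NA_character_,
                       start_mm = NA_real_, stimulus_mm = NA_real_,
                       stimulus_source = sources, response = NA_character_,
                       alpha_hat_mm = NA_real_, beta_hat_mm = NA_real_,
                       stringsAsFactors = FALSE)
  cp <- data.frame(checkpoint = config$checkpoints,
                   alpha_hat_mm = NA_real_, beta_hat_mm = NA_real_)

  for (t in seq_len(n)) {
    direction <- direction_from_start(start_labels[t])
    stimulus <- switch(sources[t],
      psi = select_stimulus(post, tables),
      far = preselected_stimulus("far", est$alpha_hat, config),
      near = preselected_stimulus("near", est$alpha_hat, config))
    start <- sample_start_position(direction, stimulus, config)
    response <- responder(stimulus, direction)
    if (!response %in% c("left", "right"))
      stop_psiprop("responder must return \"left\" or \"right\"")
    post <- update_posterior(post, tables, stimulus, response)
    est <- marginal_means(post)
    trials$direction[t] <- direction
    trials$start_mm[t] <- start
    trials$stimulus_mm[t] <- stimulus
    trials$response[t] <- response
    trials$alpha_hat_mm[t] <- est$alpha_hat
    trials$beta_hat_mm[t] <- est$beta_hat
    hit <- match(t, cp$checkpoint)
    if (!is.na(hit)) {
      cp$alpha_hat_mm[hit] <- est$alpha_hat
      cp$beta_hat_mm[hit] <- est$beta_hat
    }
  }
  structure(list(participant_id = participant_id, test_id = as.integer(test_id),
                 baseline_offset_mm = as.integer(baseline_offset_mm),
                 trials = trials, checkpoints = cp, posterior = post,
                 config = config, seed = seed),
            class = "psi_session")
}

#' @export
print.psi_session <- function(x, ...) {
  fin <- x$trials[nrow(x$trials), ]
  cat(sprintf("2AFC session: participant %s, test %d, %d trials\n",
              x$participant_id, x$test_id, nrow(x$trials)))
  cat(sprintf("  final estimates: PSE = %.2f mm, uncertainty = %.2f mm\n",
              fin$alpha_hat_mm, fin$beta_hat_mm))
  cat(sprintf("  stimulus sources: %s\n",
              paste(sprintf("%s=%d", names(table(x$trials$stimulus_source)),
                            as.integer(table(x$trials$stimulus_source))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.psi_session <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$trials$trial, x$trials$alpha_hat_mm, type = "l", col = "steelblue",
       xlab = "Trial", ylab = "Estimate (mm)",
       ylim = range(c(x$trials$alpha_hat_mm, x$trials$beta_hat_mm)),
       main = "Estimate trajectory", ...)
  lines(x$trials$trial, x$trials$beta_hat_mm, col = "firebrick")
  legend("topright", c("PSE", "uncertainty"), col = c("steelblue", "firebrick"),
         lty = 1, bty = "n")
  est <- marginal_estimates(x$posterior)
  s <- seq(-100, 100, length.out = 200)
  plot(s, stats::pnorm(s, est$alpha_hat, est$beta_hat), type = "l",
       xlab = "Foot position difference (mm)", ylab = "P(judge left forward)",
       main = "Fitted psychometric function")
  agg <- aggregate(response == "left" ~ stimulus_mm, data = x$trials, FUN = mean)
  points(agg[[1]], agg[[2]], pch = 19, col = "grey40")
  invisible(x)
}
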