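#' Simulated 2AFC observer
#'
#' A synthetic responder whose probability of judging "left foot forward"
#' follows the normal-CDF psychometric model, optionally with a
#' movement-direction response bias: the effective PSE is shifted by
#' `+direction_bias/2` on backward trials and `-direction_bias/2` on forward
#' trials. Zero bias is the validated case; nonzero bias models the confound
#' the balanced direction schedule is designed to wash out.
#'
#' @param alpha,beta True psychometric parameters (mm); see
#'   [psychometric_params()].
#' @param direction_bias Full PSE shift (mm) between forward and backward
#'   movements (default 0).
#' @return An object of class `"observer_spec"`.
#' @examples
#' observer_spec(12, 18)
#' @export
observer_spec <- function(alpha, beta, direction_bias = 0) {
  params <- psychometric_params(alpha, beta)
  if (!is.finite(direction_bias))
    stop_psiprop("`direction_bias` must be finite")
  structure(list(params = params, direction_bias = as.numeric(direction_bias)),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf("Simulated observer: alpha = %.1f mm, beta = %.1f mm, direction bias = %.1f mm\n",
              x$params$alpha, x$params$beta, x$direction_bias))
  invisible(x)
}

#' Draw one simulated 2AFC response
#'
#' @param observer An [observer_spec()].
#' @param stimulus Stimulus position (mm).
#' @param direction `"forward"` or `"backward"` movement to the stimulus.
#' @return `"left"` or `"right"`.
#' @export
simulate_response <- function(observer, stimulus, direction) {
  if (!inherits(observer, "observer_spec"))
    stop_psiprop("`observer` must be an observer_spec")
  direction <- match.arg(direction, c("forward", "backward"))
  shift <- if (direction == "backward") observer$direction_bias / 2 else -observer$direction_bias / 2
  p_left <- stats::pnorm(stimulus, observer$params$alpha + shift, observer$params$beta)
  if (stats::runif(1) < p_left) "left" else "right"
}

#' Responder callback for [run_session()]
#'
#' @param observer An [observer_spec()].
#' @return A function `(stimulus, direction) -> "left" | "right"`.
#' @export
make_responder <- function(observer) {
  force(observer)
  function(stimulus, direction) simulate_response(observer, stimulus, direction)
}

#' Cohort specification for test-retest simulation
#'
#' Population structure for a simulated test-retest study. Defaults emulate
#' the young-adult cohort scale: 13 participants, PSE drawn from
#' Normal(12, 16) mm and uncertainty from Normal(18, 7) mm truncated to
#' positive values, no systematic drift between the two tests, and no
#' movement-direction bias.
#'
#' @param n_participants Number of participants.
#' @param alpha_mean,alpha_sd Population mean/SD of the true PSE (mm).
#' @param beta_mean,beta_sd Population mean/SD of the true uncertainty (mm);
#'   draws are truncated to be strictly positive.
#' @param alpha_drift,beta_drift Systematic shift of the true parameters
#'   between Test 1 and Test 2 (mm); zero means identical truth.
#' @param direction_bias Movement-direction bias passed to every observer.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 13, alpha_mean = 12, alpha_sd = 16,
                        beta_mean = 18, beta_sd = 7,
                        alpha_drift = 0, beta_drift = 0,
                        direction_bias = 0) {
  if (n_participants < 1) stop_psiprop("`n_participants` must be >= 1")
  if (alpha_sd < 0 || beta_sd < 0) stop_psiprop("population SDs must be >= 0")
  if (beta_mean <= 0) stop_psiprop("`beta_mean` must be positive")
  structure(list(n_participants = as.integer(n_participants),
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 alpha_drift = alpha_drift, beta_drift = beta_drift,
                 direction_bias = direction_bias),
            class = "cohort_spec")
}

# beta truncated-normal draw (> eps)
draw_positive_normal <- function(mean, sd, eps = 0.5) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > eps) return(x)
  }
}

#' Simulate a full test-retest cohort
#'
#' Draws each participant's true (alpha, beta) from the population, then runs
#' the full adaptive protocol twice per participant (Test 1 and Test 2, with
#' the truth shifted by the drift parameters on Test 2). Returns the paired
#' session records together with the ground-truth table for recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @param config A [protocol_config()].
#' @param grid A [parameter_grid()] for the engine.
#' @param seed Optional integer seed making the whole cohort reproducible.
#' @return An object of class `"psi_cohort"`: list of `psi_session`s
#'   (`$sessions`, two per participant), ground truth (`$truth`), the specs
#'   and the seed.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_spec(n_participants = 3), seed = 7)
#' coh$truth
#' }
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = protocol_config(),
                            grid = parameter_grid(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) stop_psiprop("`spec` must be a cohort_spec")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tables <- likelihood_tables(grid, config$stimuli)
  sessions <- vector("list", 2L * spec$n_participants)
  truth <- vector("list", 2L * spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    pid <- sprintf("P%02d", i)
    alpha1 <- stats::rnorm(1, spec$alpha_mean, spec$alpha_sd)
    beta1 <- draw_positive_normal(spec$beta_mean, spec$beta_sd)
    for (test in 1:2) {
      alpha <- alpha1 + (test - 1) * spec$alpha_drift
      beta <- max(beta1 + (test - 1) * spec$beta_drift, 0.5)
      obs <- observer_spec(alpha, beta, spec$direction_bias)
      k <- 2L * (i - 1L) + test
      sessions[[k]] <- run_session(make_responder(obs), config, grid,
                                   participant_id = pid, test_id = test,
                                   tables = tables)
      truth[[k]] <- data.frame(participant_id = pid, test_id = test,
                               alpha_true_mm = alpha, beta_true_mm = beta)
    }
  }
  structure(list(sessions = sessions, truth = do.call(rbind, truth),
                 spec = spec, config = config, seed = seed),
            class = "psi_cohort")
}

#' @export
print.psi_cohort <- function(x, ...) {
  cat(sprintf("Simulated test-retest cohort: %d participants x 2 sessions x %d trials\n",
              x$spec$n_participants, x$config$n_trials))
  cat(sprintf("  population truth: alpha ~ N(%.1f, %.1f) mm, beta ~ N+(%.1f, %.1f) mm\n",
              x$spec$alpha_mean, x$spec$alpha_sd, x$spec$beta_mean, x$spec$beta_sd))
  invisible(x)
}
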