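#' Psychometric function parameters
#'
#' Bundles the two parameters of a 2AFC observer's psychometric function for
#' foot position difference: `alpha`, the point of subjective equality (PSE),
#' and `beta`, the uncertainty. Both are in millimetres of foot position
#' difference (left minus right ankle marker along the walking axis, so
#' positive values mean the left foot is forward).
#'
#' @param alpha PSE in mm. The stimulus at which the observer judges "left
#'   foot forward" with probability exactly 0.5.
#' @param beta Uncertainty in mm: the standard deviation of the normal CDF.
#'   Must be strictly positive. Inversely related to the slope of the
#'   psychometric function; larger values mean noisier position sense.
#' @return An object of class `"psychometric_params"`.
#' @examples
#' psychometric_params(12, 18.2)
#' @export
psychometric_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop_psiprop("`alpha` must be a single finite number (mm)")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop_psiprop("`beta` must be a single finite number (mm)")
  if (beta <= 0)
    stop_psiprop("`beta` must be strictly positive (it is the SD of the psychometric CDF)")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "psychometric_params")
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(sprintf("Psychometric parameters: PSE alpha = %.2f mm, uncertainty beta = %.2f mm\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Probability of a "left foot forward" judgement
#'
#' The psychometric model: the probability that the observer reports the left
#' (test) foot as more forward at stimulus `s` is the normal CDF
#' `Phi((s - alpha) / beta)`. There are no lapse or guess parameters; at the
#' extreme stimuli (+/-100 mm) responses are effectively deterministic for
#' realistic parameter values.
#'
#' @param stimulus Stimulus position(s) in mm of foot position difference.
#' @param params A [psychometric_params()] object.
#' @return Probability (vector) in `[0, 1]` of a "left" response.
#' @examples
#' p <- psychometric_params(12, 18.2)
#' response_probability(12, p)    # 0.5 at the PSE
#' response_probability(-100, p)  # essentially 0
#' @export
response_probability <- function(stimulus, params) {
  if (!inherits(params, "psychometric_params"))
    stop_psiprop("`params` must be a psychometric_params object")
  stats::pnorm(stimulus, mean = params$alpha, sd = params$beta)
}

#' Stimulus grid
#'
#' The set of foot-position-difference locations the treadmill can present.
#' The default is the canonical grid of 21 locations: every 10 mm from -100
#' to +100 mm.
#'
#' @param locations Strictly ascending, unique, finite stimulus values (mm).
#' @return A numeric vector of class `"stimulus_grid"`.
#' @export
stimulus_grid <- function(locations = seq(-100, 100, by = 10)) {
  locations <- as.numeric(locations)
  if (length(locations) < 2L || any(!is.finite(locations)))
    stop_psiprop("stimulus grid needs at least two finite locations")
  if (any(diff(locations) <= 0))
    stop_psiprop("stimulus locations must be strictly ascending and unique")
  structure(locations, class = "stimulus_grid")
}

#' Candidate parameter grid for the Psi engine
#'
#' Discretisation of the (alpha, beta) space over which the engine maintains
#' its joint posterior. The defaults cover PSE values across the full
#' stimulus range at 1 mm resolution and uncertainty values from 0.5 to
#' 150 mm at 0.5 mm resolution, wide enough that the exponential prior's
#' truncated mean stays within half a millimetre of its nominal 20 mm.
#'
#' @param alpha_values Strictly ascending candidate PSE values (mm),
#'   symmetric about 0.
#' @param beta_values Strictly ascending, strictly positive candidate
#'   uncertainty values (mm).
#' @return An object of class `"parameter_grid"`.
#' @export
parameter_grid <- function(alpha_values = seq(-100, 100, by = 1),
                           beta_values = seq(0.5, 150, by = 0.5)) {
  alpha_values <- as.numeric(alpha_values)
  beta_values <- as.numeric(beta_values)
  if (length(alpha_values) < 1L || length(beta_values) < 1L)
    stop_psiprop("parameter grid must be non-empty")
  if (any(!is.finite(alpha_values)) || any(!is.finite(beta_values)))
    stop_psiprop("parameter grid values must be finite")
  if (any(diff(alpha_values) <= 0) || (length(beta_values) > 1L && any(diff(beta_values) <= 0)))
    stop_psiprop("parameter grid values must be strictly ascending")
  if (any(beta_values <= 0))
    stop_psiprop("all candidate beta values must be strictly positive")
  if (max(abs(alpha_values + rev(alpha_values))) > 1e-8)
    stop_psiprop("alpha grid must be symmetric about 0")
  structure(list(alpha_values = alpha_values, beta_values = beta_values),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("Parameter grid: %d alpha values in [%g, %g] mm x %d beta values in [%g, %g] mm\n",
              length(x$alpha_values), min(x$alpha_values), max(x$alpha_values),
              length(x$beta_values), min(x$beta_values), max(x$beta_values)))
  invisible(x)
}

#' Precomputed response-likelihood lookup tables
#'
#' For every grid cell (alpha, beta) and stimulus s, tabulates the likelihood
#' of each response: `left[a, b, s] = Phi((s - alpha_a) / beta_b)` and
#' `right = 1 - left`. The Psi engine indexes into these tables on every
#' trial instead of re-evaluating the CDF.
#'
#' @param grid A [parameter_grid()].
#' @param stimuli A [stimulus_grid()].
#' @return An object of class `"likelihood_tables"`: list with 3-d arrays
#'   `left` and `right` (alpha x beta x stimulus) plus the grids.
#' @export
likelihood_tables <- function(grid = parameter_grid(), stimuli = stimulus_grid()) {
  if (!inherits(grid, "parameter_grid")) stop_psiprop("`grid` must be a parameter_grid")
  if (!inherits(stimuli, "stimulus_grid")) stop_psiprop("`stimuli` must be a stimulus_grid")
  na <- length(grid$alpha_values)
  nb <- length(grid$beta_values)
  ns <- length(stimuli)
  a <- matrix(grid$alpha_values, na, nb)
  b <- matrix(grid$beta_values, na, nb, byrow = TRUE)
  left <- array(NA_real_, dim = c(na, nb, ns))
  for (k in seq_len(ns)) {
    left[, , k] <- stats::pnorm((unclass(stimuli)[k] - a) / b)
  }
  structure(list(left = left, right = 1 - left, grid = grid,
                 stimuli = stimuli),
            class = "likelihood_tables")
}

# Index of `stimulus` in the table's stimulus grid, or an error.
stimulus_index <- function(tables, stimulus) {
  k <- which(abs(unclass(tables$stimuli) - stimulus) < 1e-9)
  if (length(k) != 1L)
    stop_psiprop("stimulus ", stimulus, " mm is not on the stimulus grid")
  k
}
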