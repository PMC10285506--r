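#' Initial joint prior over (alpha, beta)
#'
#' Builds the engine's starting posterior: independent maximum-entropy style
#' priors, alpha ~ Normal(0, 20 mm) and beta ~ Exponential(mean 20 mm),
#' discretised by evaluating each density at the grid points and
#' renormalising. On the default grid the alpha marginal has mean 0 and SD
#' very close to 20 mm, and the beta marginal mean sits within about 0.2 mm
#' of 20 (discretisation/truncation).
#'
#' @param grid A [parameter_grid()].
#' @param alpha_prior_mean,alpha_prior_sd Normal prior on the PSE (mm).
#' @param beta_prior_mean Mean of the exponential prior on the uncertainty (mm).
#' @return An object of class `"psi_posterior"`: the grid plus a matrix of
#'   probability mass (rows alpha, columns beta) summing to one.
#' @examples
#' post <- init_posterior()
#' marginal_estimates(post)
#' @export
init_posterior <- function(grid = parameter_grid(), alpha_prior_mean = 0,
                           alpha_prior_sd = 20, beta_prior_mean = 20) {
  if (!inherits(grid, "parameter_grid")) stop_psiprop("`grid` must be a parameter_grid")
  if (alpha_prior_sd <= 0 || beta_prior_mean <= 0)
    stop_psiprop("prior scale parameters must be positive")
  wa <- stats::dnorm(grid$alpha_values, alpha_prior_mean, alpha_prior_sd)
  wb <- stats::dexp(grid$beta_values, rate = 1 / beta_prior_mean)
  mass <- outer(wa, wb)
  new_psi_posterior(grid, mass / sum(mass))
}

new_psi_posterior <- function(grid, mass) {
  structure(list(grid = grid, mass = mass), class = "psi_posterior")
}

#' @export
print.psi_posterior <- function(x, ...) {
  est <- marginal_estimates(x)
  cat(sprintf(
    "Psi joint posterior on %d x %d grid\n  alpha_hat = %.2f mm, beta_hat = %.2f mm, entropy = %.3f bits\n",
    length(x$grid$alpha_values), length(x$grid$beta_values),
    est$alpha_hat, est$beta_hat, est$entropy_bits))
  invisible(x)
}

# -sum(p log2 p) with 0 log 0 := 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information entropy of a posterior (bits)
#'
#' Shannon entropy, `-sum(p * log2(p))` with `0 * log2(0) := 0`, of a
#' `psi_posterior` or of a raw probability vector. This is the quantity the
#' stimulus-selection rule drives down.
#'
#' @param x A `psi_posterior` or a numeric vector of probability masses.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' entropy(rep(0.25, 4))  # 2 bits
#' @export
entropy <- function(x) {
  if (inherits(x, "psi_posterior")) x <- x$mass
  if (any(x < -1e-12)) stop_psiprop("probability masses must be non-negative")
  entropy_bits(as.numeric(x))
}

#' Expected posterior entropy after one trial at a stimulus
#'
#' For a candidate stimulus, updates the posterior under each hypothetical
#' response ("left", "right"), computes the entropy of each branch posterior,
#' and averages the two weighted by their predictive probabilities under the
#' current posterior. The Psi rule presents the stimulus minimising this
#' quantity.
#'
#' @param posterior A `psi_posterior`.
#' @param tables [likelihood_tables()] built on the same grids.
#' @param stimulus A stimulus on the table's stimulus grid (mm).
#' @return Expected entropy in bits.
#' @export
expected_entropy <- function(posterior, tables, stimulus) {
  check_engine_inputs(posterior, tables)
  k <- stimulus_index(tables, stimulus)
  eh <- 0
  for (resp in c("left", "right")) {
    u <- posterior$mass * tables[[resp]][, , k]
    p_resp <- sum(u)
    if (p_resp > 0) eh <- eh + p_resp * entropy_bits(u / p_resp)
  }
  eh
}

#' Expected entropy profile over all candidate stimuli
#'
#' Vectorised scan (compiled kernel) of [expected_entropy()] across every
#' stimulus on the grid; the engine's per-trial hot loop.
#'
#' @inheritParams expected_entropy
#' @return Numeric vector of expected entropies (bits), one per stimulus.
#' @export
expected_entropies <- function(posterior, tables) {
  check_engine_inputs(posterior, tables)
  .psi_entropy_scan(posterior$mass, tables$left, length(tables$stimuli))
}

#' Select the next stimulus by expected-entropy minimisation
#'
#' Returns the candidate stimulus whose one-trial-ahead expected posterior
#' entropy is smallest; ties are broken deterministically in favour of the
#' smallest stimulus value so that runs are exactly reproducible.
#'
#' @inheritParams expected_entropy
#' @return A stimulus location (mm).
#' @export
select_stimulus <- function(posterior, tables) {
  eh <- expected_entropies(posterior, tables)
  # ties (within numerical noise) go to the smallest stimulus value
  k <- which(eh <= min(eh) + 1e-12)[1]
  unclass(tables$stimuli)[k]
}

#' Bayes update of the joint posterior after a response
#'
#' Multiplies the current mass by the response likelihood at the presented
#' stimulus and renormalises; the posterior for trial t becomes the prior for
#' trial t + 1.
#'
#' @inheritParams expected_entropy
#' @param response `"left"` or `"right"`.
#' @return The updated `psi_posterior`.
#' @export
update_posterior <- function(posterior, tables, stimulus, response) {
  check_engine_inputs(posterior, tables)
  response <- match.arg(response, c("left", "right"))
  k <- stimulus_index(tables, stimulus)
  u <- posterior$mass * tables[[response]][, , k]
  z <- sum(u)
  if (z <= 0)
    stop_psiprop("response has zero likelihood everywhere on the grid; cannot update")
  new_psi_posterior(posterior$grid, u / z)
}

#' Marginal-mean parameter estimates
#'
#' The engine's running estimates: the mean of the alpha marginal (PSE
#' estimate), the mean of the beta marginal (uncertainty estimate), and the
#' current joint entropy in bits.
#'
#' @param posterior A `psi_posterior`.
#' @return List with `alpha_hat`, `beta_hat` (mm) and `entropy_bits`.
#' @export
marginal_estimates <- function(posterior) {
  if (!inherits(posterior, "psi_posterior"))
    stop_psiprop("`posterior` must be a psi_posterior")
  list(alpha_hat = sum(rowSums(posterior$mass) * posterior$grid$alpha_values),
       beta_hat = sum(colSums(posterior$mass) * posterior$grid$beta_values),
       entropy_bits = entropy_bits(as.numeric(posterior$mass)))
}

# cheap per-trial running estimates (no entropy) for the session loop
marginal_means <- function(posterior) {
  list(alpha_hat = sum(rowSums(posterior$mass) * posterior$grid$alpha_values),
       beta_hat = sum(colSums(posterior$mass) * posterior$grid$beta_values))
}

check_engine_inputs <- function(posterior, tables) {
  if (!inherits(posterior, "psi_posterior"))
    stop_psiprop("`posterior` must be a psi_posterior")
  if (!inherits(tables, "likelihood_tables"))
    stop_psiprop("`tables` must be likelihood_tables")
  if (!identical(dim(posterior$mass), dim(tables$left)[1:2]))
    stop_psiprop("posterior grid and likelihood tables have different shapes")
  invisible(TRUE)
}
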