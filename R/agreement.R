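#' MCMC sampler configuration
#'
#' Defaults follow the analysis convention used throughout the package:
#' 10,000 retained draws in each of 4 chains (40,000 total) after 2,000
#' adaptation/warm-up iterations per chain, with a fixed seed for
#' reproducibility.
#'
#' @param draws Retained posterior draws per chain.
#' @param chains Number of chains.
#' @param tuning Adaptation/warm-up iterations per chain (discarded).
#' @param seed Integer seed for the chain RNGs.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(draws = 10000, chains = 4, tuning = 2000, seed = 1L) {
  if (draws < 1 || chains < 1 || tuning < 1)
    stop_psiprop("`draws`, `chains` and `tuning` must all be positive")
  structure(list(draws = as.integer(draws), chains = as.integer(chains),
                 tuning = as.integer(tuning), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Fit a JAGS model and return pooled draws (matrix, one column per monitored
# parameter) plus convergence diagnostics (split-chain R-hat via coda, ESS).
run_jags <- function(model_string, data, monitor, mcmc, diag_transform = NULL) {
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + ch)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = mcmc$chains,
                             n.adapt = mcmc$tuning, quiet = TRUE)
  samples <- rjags::coda.samples(model, variable.names = monitor,
                                 n.iter = mcmc$draws)
  draws <- do.call(rbind, lapply(samples, as.matrix))
  # diagnostics may be computed on a transform of the monitored parameters
  # (e.g. only the identified combinations of an over-parameterised model)
  diag_samples <- if (is.null(diag_transform)) samples else
    coda::as.mcmc.list(lapply(samples, function(m) coda::mcmc(diag_transform(as.matrix(m)))))
  rhat <- tryCatch({
    if (mcmc$chains > 1) {
      g <- coda::gelman.diag(diag_samples, autoburnin = FALSE, multivariate = FALSE)
      stats::setNames(g$psrf[, 1], rownames(g$psrf))
    } else NULL
  }, error = function(e) NULL)
  ess <- tryCatch(coda::effectiveSize(diag_samples), error = function(e) NULL)
  # zero-variance chains (degenerate data) give non-finite psrf; only
  # finite exceedances are treated as convergence failures
  high <- !is.null(rhat) && any(is.finite(rhat) & rhat >= 1.01)
  converged <- !high
  if (high)
    warning("MCMC convergence flag: split R-hat > 1.01 for ",
            paste(names(rhat)[is.finite(rhat) & rhat >= 1.01], collapse = ", "),
            call. = FALSE)
  list(draws = draws, rhat = rhat, ess = ess, converged = converged,
       n_retained = nrow(draws), chains = mcmc$chains,
       tuning_per_chain = mcmc$tuning)
}

#' Highest density interval of posterior draws
#'
#' The narrowest contiguous window of the sorted draws containing
#' `ceiling(mass * n)` of them.
#'
#' @param draws Numeric vector of posterior draws (at least 2).
#' @param mass Probability mass to cover (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 2L) stop_psiprop("`draws` must contain at least 2 values")
  if (mass <= 0 || mass >= 1) stop_psiprop("`mass` must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Fraction of posterior draws inside a ROPE
#'
#' Proportion of draws falling inside the closed interval
#' `[low, high]` — the region of practical equivalence around a null value.
#'
#' @param draws Numeric vector of posterior draws.
#' @param low,high ROPE bounds, `low <= high`.
#' @return Fraction in `[0, 1]`.
#' @export
rope_fraction <- function(draws, low, high) {
  if (low > high) stop_psiprop("`low` must be <= `high`")
  mean(draws >= low & draws <= high)
}

new_posterior_summary <- function(name, draws, rope = NULL) {
  h <- hdi(draws, 0.95)
  structure(list(parameter = name, mean = mean(draws),
                 hdi_low = h[1], hdi_high = h[2],
                 rope_low = if (is.null(rope)) NA_real_ else rope[1],
                 rope_high = if (is.null(rope)) NA_real_ else rope[2],
                 rope_fraction = if (is.null(rope)) NA_real_ else
                   rope_fraction(draws, rope[1], rope[2]),
                 draws = draws),
            class = "posterior_summary")
}

#' Summarise posterior draws (mean, 95% HDI, ROPE fraction)
#'
#' @param draws Numeric vector of posterior draws.
#' @param name Parameter label.
#' @param rope Optional `c(low, high)` region of practical equivalence.
#' @return An object of class `"posterior_summary"`.
#' @export
posterior_summary <- function(draws, name = "parameter", rope = NULL) {
  new_posterior_summary(name, as.numeric(draws), rope)
}

#' @export
print.posterior_summary <- function(x, digits = 2, ...) {
  cat(format_summary(x, digits), "\n")
  invisible(x)
}

format_summary <- function(x, digits = 2) {
  s <- sprintf("%s: %.*f [%.*f, %.*f]", x$parameter, digits, x$mean,
               digits, x$hdi_low, digits, x$hdi_high)
  if (!is.na(x$rope_fraction))
    s <- sprintf("%s (%.1f%% in ROPE [%g, %g])", s, 100 * x$rope_fraction,
                 x$rope_low, x$rope_high)
  s
}

#' Limits of agreement
#'
#' Bland-Altman limits: mean of the paired differences plus/minus 1.96 times
#' their sample standard deviation (n - 1 denominator).
#'
#' @param differences Per-participant Test 2 minus Test 1 differences (mm).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' limits_of_agreement(c(-1, 1))  # +/- 1.96 * sqrt(2)
#' @export
limits_of_agreement <- function(differences) {
  differences <- as.numeric(differences)
  if (length(differences) < 2L)
    stop_psiprop("need at least 2 differences for limits of agreement")
  m <- mean(differences)
  s <- stats::sd(differences)
  c(low = m - 1.96 * s, high = m + 1.96 * s)
}

# weakly-informative scales from the data, guarding degenerate inputs
data_scale <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) s <- max(abs(y), 1)
  s
}

#' Bayesian mean-bias model
#'
#' Models the per-participant Test 2 minus Test 1 differences as
#' `Normal(mu, sigma)` and summarises the posterior of the mean bias `mu`
#' against a region of practical equivalence (default +/-5 mm). Priors are
#' weakly informative and scaled to the data SD: `mu ~ Normal(0, 10 * sd)`,
#' `sigma ~ Exponential(mean = sd)`.
#'
#' @param differences Numeric vector of paired differences (mm), `n >= 3`.
#' @param mcmc An [mcmc_config()].
#' @param rope ROPE for `mu` (mm).
#' @return Object of class `"bayes_fit"` with `$mu` and `$sigma`
#'   [posterior_summary()]s, the pooled draws and diagnostics.
#' @export
fit_mean_bias <- function(differences, mcmc = mcmc_config(), rope = c(-5, 5)) {
  y <- as.numeric(differences)
  if (length(y) < 3L) stop_psiprop("need at least 3 differences")
  s0 <- data_scale(y)
  model <- "
model {
  for (i in 1:N) { y[i] ~ dnorm(mu, tau) }
  mu ~ dnorm(0, prec_mu)
  sigma ~ dexp(rate_sigma) T(sigma_lo, )
  tau <- 1 / (sigma * sigma)
}"
  fit <- run_jags(model, list(y = y, N = length(y),
                              prec_mu = 1 / (10 * s0)^2, rate_sigma = 1 / s0,
                              sigma_lo = 1e-6 * s0),
                  c("mu", "sigma"), mcmc)
  structure(list(model = "mean_bias",
                 mu = new_posterior_summary("mean bias (mm)", fit$draws[, "mu"], rope),
                 sigma = new_posterior_summary("sigma (mm)", fit$draws[, "sigma"]),
                 draws = fit$draws, diagnostics = fit[c("rhat", "ess", "converged",
                                                        "n_retained", "chains",
                                                        "tuning_per_chain")],
                 n = length(y)),
            class = "bayes_fit")
}

# shared JAGS linear regression: y ~ Normal(b + m * x, sigma)
fit_normal_regression <- function(x, y, mcmc) {
  if (length(x) != length(y)) stop_psiprop("`x` and `y` lengths differ")
  if (length(y) < 3L) stop_psiprop("need at least 3 observations")
  if (stats::sd(x) <= 0) stop_psiprop("predictor has zero variance")
  sy <- data_scale(y)
  sx <- stats::sd(x)
  xbar <- mean(x)
  model <- "
model {
  for (i in 1:N) { y[i] ~ dnorm(bc + m * xc[i], tau) }
  bc ~ dnorm(0, prec_b)
  m ~ dnorm(0, prec_m)
  sigma ~ dexp(rate_sigma) T(sigma_lo, )
  tau <- 1 / (sigma * sigma)
}"
  fit <- run_jags(model, list(y = y, xc = x - xbar, N = length(y),
                              prec_b = 1 / (10 * sy)^2,
                              prec_m = 1 / (10 * sy / sx)^2,
                              rate_sigma = 1 / sy, sigma_lo = 1e-6 * sy),
                  c("bc", "m", "sigma"), mcmc)
  # un-centre: intercept at x = 0
  draws <- cbind(b = fit$draws[, "bc"] - fit$draws[, "m"] * xbar,
                 m = fit$draws[, "m"], sigma = fit$draws[, "sigma"])
  list(draws = draws, diagnostics = fit[c("rhat", "ess", "converged",
                                          "n_retained", "chains",
                                          "tuning_per_chain")])
}

#' Bayesian bias-vs-true-score regression
#'
#' Second Bland-Altman step: regresses the Test 2 minus Test 1 difference on
#' the proxy "true score" (the participant's mean of Test 1 and Test 2).
#' Agreement bias across the measurement range shows up as a nonzero
#' intercept (ROPE +/-5 mm) or slope (ROPE +/-0.1, i.e. 1 mm of bias per
#' 10 mm of true score).
#'
#' @param true_scores Per-participant mean of the two tests (mm).
#' @param differences Per-participant Test 2 minus Test 1 differences (mm).
#' @param mcmc An [mcmc_config()].
#' @param rope_intercept,rope_slope ROPEs for the two coefficients.
#' @return Object of class `"bayes_fit"` with `$intercept` and `$slope`
#'   summaries.
#' @export
fit_bias_regression <- function(true_scores, differences, mcmc = mcmc_config(),
                                rope_intercept = c(-5, 5),
                                rope_slope = c(-0.1, 0.1)) {
  fit <- fit_normal_regression(as.numeric(true_scores), as.numeric(differences), mcmc)
  structure(list(model = "bias_regression",
                 intercept = new_posterior_summary("intercept (mm)",
                                                   fit$draws[, "b"], rope_intercept),
                 slope = new_posterior_summary("slope", fit$draws[, "m"], rope_slope),
                 sigma = new_posterior_summary("sigma (mm)", fit$draws[, "sigma"]),
                 draws = fit$draws, diagnostics = fit$diagnostics,
                 n = length(differences)),
            class = "bayes_fit")
}

#' Bayesian Test 1 vs Test 2 regression
#'
#' Secondary agreement analysis: regresses the Test 2 estimate on the Test 1
#' estimate without sharing information across tests. Perfect agreement
#' corresponds to slope 1 and intercept 0; the 95% HDIs characterise how
#' plausible that is. No ROPE is applied.
#'
#' @param test1,test2 Per-participant estimates (mm) from the two sessions.
#' @param mcmc An [mcmc_config()].
#' @return Object of class `"bayes_fit"` with `$intercept` and `$slope`
#'   summaries.
#' @export
fit_retest_regression <- function(test1, test2, mcmc = mcmc_config()) {
  fit <- fit_normal_regression(as.numeric(test1), as.numeric(test2), mcmc)
  structure(list(model = "retest_regression",
                 intercept = new_posterior_summary("intercept (mm)", fit$draws[, "b"]),
                 slope = new_posterior_summary("slope", fit$draws[, "m"]),
                 sigma = new_posterior_summary("sigma (mm)", fit$draws[, "sigma"]),
                 draws = fit$draws, diagnostics = fit$diagnostics,
                 n = length(test1)),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s model (n = %d, %d draws)\n", gsub("_", " ", x$model),
              x$n, x$diagnostics$n_retained))
  for (nm in intersect(c("mu", "intercept", "slope", "contrast", "stimulus_slope"),
                       names(x)))
    cat("  ", format_summary(x[[nm]]), "\n", sep = "")
  if (!x$diagnostics$converged) cat("  warning: split R-hat > 1.01\n")
  invisible(x)
}

#' Bayesian logistic model of movement-direction effects on responses
#'
#' Models every trial's response (left = 1) as Bernoulli with
#' `logit(p_left) = alpha_participant[i] + beta_direction[j] +
#' beta_stimulus * stimulus`, with an intercept per participant (intrinsic
#' bias to judge "left"), one coefficient per movement direction, and a
#' common stimulus slope. If movement direction does not influence
#' judgements, the two direction coefficients should be practically
#' identical; see [direction_contrast()]. Priors are weakly informative on
#' the logit scale (Normal(0, 5) for intercepts and direction coefficients,
#' Normal(0, 5/sd(stimulus)) for the slope); the stimulus is standardised
#' internally and the slope reported per mm.
#'
#' @param trials Data frame with columns `participant_id`, `direction`
#'   (`"forward"`/`"backward"`), `stimulus_mm`, `response`
#'   (`"left"`/`"right"`). Typically a pooled trial log of both tests; see
#'   [trial_log()].
#' @param mcmc An [mcmc_config()].
#' @return Object of class `"direction_bias_fit"`: draws for each
#'   participant intercept, both direction coefficients (logit scale) and
#'   the per-mm stimulus slope, plus diagnostics.
#' @export
fit_direction_bias_model <- function(trials, mcmc = mcmc_config()) {
  need <- c("participant_id", "direction", "stimulus_mm", "response")
  if (!all(need %in% names(trials)))
    stop_psiprop("`trials` must have columns ", paste(need, collapse = ", "))
  pid <- factor(trials$participant_id)
  if (nlevels(pid) < 2L) stop_psiprop("need at least 2 participants")
  dir <- factor(trials$direction, levels = c("forward", "backward"))
  if (any(is.na(dir))) stop_psiprop("`direction` must be forward/backward")
  if (nlevels(droplevels(dir)) < 2L)
    stop_psiprop("both movement directions must be present")
  y <- as.integer(trials$response == "left")
  x <- as.numeric(trials$stimulus_mm)
  sx <- stats::sd(x)
  model <- "
model {
  for (t in 1:N) {
    y[t] ~ dbern(p[t])
    logit(p[t]) <- a[part[t]] + b[dir[t]] + bs * xs[t]
  }
  for (i in 1:NP) { a[i] ~ dnorm(0, 0.04) }
  for (j in 1:2) { b[j] ~ dnorm(0, 0.04) }
  bs ~ dnorm(0, 0.04)
}"
  # Individual a[i] and b[j] are only weakly identified (a constant can move
  # between them); convergence is judged on the identified combinations.
  identified <- function(m) {
    bbar <- (m[, "b[1]"] + m[, "b[2]"]) / 2
    out <- cbind(m[, grep("^a\\[", colnames(m)), drop = FALSE] + bbar,
                 contrast = m[, "b[2]"] - m[, "b[1]"],
                 b_stimulus = m[, "bs"])
    colnames(out) <- c(paste0("intercept[", seq_len(nlevels(pid)), "]"),
                       "contrast", "b_stimulus")
    out
  }
  fit <- run_jags(model, list(y = y, xs = x / sx, part = as.integer(pid),
                              dir = as.integer(dir), N = length(y),
                              NP = nlevels(pid)),
                  c("a", "b", "bs"), mcmc, diag_transform = identified)
  draws <- fit$draws
  colnames(draws)[colnames(draws) == "b[1]"] <- "b_forward"
  colnames(draws)[colnames(draws) == "b[2]"] <- "b_backward"
  draws[, "bs"] <- draws[, "bs"] / sx  # per-mm slope
  colnames(draws)[colnames(draws) == "bs"] <- "b_stimulus"
  structure(list(model = "direction_bias", draws = draws,
                 participants = levels(pid),
                 stimulus_slope = new_posterior_summary("stimulus slope (logit/mm)",
                                                        draws[, "b_stimulus"]),
                 diagnostics = fit[c("rhat", "ess", "converged", "n_retained",
                                     "chains", "tuning_per_chain")],
                 n = length(y)),
            class = "direction_bias_fit")
}

#' @export
print.direction_bias_fit <- function(x, ...) {
  cat(sprintf("Direction-bias logistic model: %d trials, %d participants, %d draws\n",
              x$n, length(x$participants), x$diagnostics$n_retained))
  print(direction_contrast(x))
  cat("  ", format_summary(x$stimulus_slope), "\n", sep = "")
  invisible(x)
}

#' Movement-direction contrast
#'
#' Posterior of `beta_direction[backward] - beta_direction[forward]` on the
#' coefficient (logit) scale, summarised against a ROPE of +/-0.5. A
#' contrast concentrated inside the ROPE indicates that responses were not
#' biased by movement direction.
#'
#' @param fit A [fit_direction_bias_model()] result (or any object with a
#'   `draws` matrix holding `b_forward` and `b_backward` columns).
#' @param rope ROPE bounds for the contrast.
#' @return A [posterior_summary()].
#' @export
direction_contrast <- function(fit, rope = c(-0.5, 0.5)) {
  draws <- fit$draws
  if (!all(c("b_forward", "b_backward") %in% colnames(draws)))
    stop_psiprop("`fit` draws must contain b_forward and b_backward")
  new_posterior_summary("direction contrast (backward - forward)",
                        draws[, "b_backward"] - draws[, "b_forward"], rope)
}

#' Intraclass correlation ICC(2,1) with 95% CI
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC from the
#' two-way ANOVA mean squares, with the standard F-based confidence interval.
#'
#' @param test1,test2 Per-participant estimates from the two sessions
#'   (`n >= 3`).
#' @param conf_level Confidence level for the interval.
#' @return Object of class `"icc"`: `icc`, `ci_low`, `ci_high`, the mean
#'   squares, and a `degenerate` flag set when the error variance collapses.
#' @export
icc_2_1 <- function(test1, test2, conf_level = 0.95) {
  y <- cbind(as.numeric(test1), as.numeric(test2))
  if (any(!is.finite(y))) stop_psiprop("estimates must be finite")
  n <- nrow(y)
  k <- ncol(y)
  if (n < 3L) stop_psiprop("need at least 3 participants")
  grand <- mean(y)
  rowm <- rowMeans(y)
  colm <- colMeans(y)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((y - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  degenerate <- !is.finite(denom) || denom <= 0 || mse <= 0
  icc <- if (denom > 0) (msr - mse) / denom else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!degenerate) {
    # Shrout-Fleiss / McGraw-Wong F-based interval for ICC(A,1)
    alpha <- 1 - conf_level
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 ms = c(rows = msr, cols = msc, error = mse),
                 n = n, k = k, conf_level = conf_level,
                 degenerate = degenerate),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.2f [%.2f, %.2f] (n = %d)%s\n", x$icc, x$ci_low,
              x$ci_high, x$n,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}
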