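#' Checkpoint estimate table for a set of sessions
#'
#' Flattens sessions into the session-summary layout: one row per
#' participant, test and checkpoint with the engine estimates recorded at
#' that trial.
#'
#' @param x A `psi_cohort`, a list of `psi_session`s, a single
#'   `psi_session`, or an already-flat data frame with columns
#'   `participant_id`, `test_id`, `checkpoint`, `alpha_hat_mm`,
#'   `beta_hat_mm` (returned unchanged).
#' @return A data frame in the session-summary layout.
#' @export
session_summary <- function(x) {
  if (is.data.frame(x)) {
    need <- c("participant_id", "test_id", "checkpoint", "alpha_hat_mm", "beta_hat_mm")
    if (!all(need %in% names(x)))
      stop_psiprop("summary data frame must have columns ", paste(need, collapse = ", "))
    return(x[need])
  }
  if (inherits(x, "psi_cohort")) x <- x$sessions
  if (inherits(x, "psi_session")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "psi_session")))
    stop_psiprop("`x` must be psi_session(s), a psi_cohort, or a summary data frame")
  do.call(rbind, lapply(x, function(s) {
    data.frame(participant_id = s$participant_id, test_id = s$test_id,
               checkpoint = s$checkpoints$checkpoint,
               alpha_hat_mm = s$checkpoints$alpha_hat_mm,
               beta_hat_mm = s$checkpoints$beta_hat_mm,
               stringsAsFactors = FALSE)
  }))
}

#' Paired Test 1 / Test 2 estimates for one parameter at one checkpoint
#'
#' Assembles the agreement-analysis input: for each participant, the
#' estimate of one psychometric parameter from each of the two sessions,
#' together with the Bland-Altman derived quantities — the difference
#' (Test 2 minus Test 1) and the "true score" proxy (the mean of the two
#' tests).
#'
#' @param x Sessions in any form accepted by [session_summary()].
#' @param checkpoint Trial checkpoint (e.g. 25, 50, 75).
#' @param parameter `"alpha"` (PSE) or `"beta"` (uncertainty).
#' @return A data frame of class `"paired_estimates"` with columns
#'   `participant_id`, `test1`, `test2`, `difference`, `true_score`.
#' @export
paired_estimates <- function(x, checkpoint = 75, parameter = c("alpha", "beta")) {
  parameter <- match.arg(parameter)
  tab <- session_summary(x)
  tab <- tab[tab$checkpoint == checkpoint, ]
  if (nrow(tab) == 0L)
    stop_psiprop("no estimates recorded at checkpoint ", checkpoint)
  col <- if (parameter == "alpha") "alpha_hat_mm" else "beta_hat_mm"
  wide <- merge(tab[tab$test_id == 1, c("participant_id", col)],
                tab[tab$test_id == 2, c("participant_id", col)],
                by = "participant_id", suffixes = c("_1", "_2"))
  missing1 <- setdiff(tab$participant_id[tab$test_id == 2], wide$participant_id)
  missing2 <- setdiff(tab$participant_id[tab$test_id == 1], wide$participant_id)
  unpaired <- union(missing1, missing2)
  if (length(unpaired) > 0L)
    stop_psiprop("unpaired participants (missing one session): ",
                 paste(sort(unpaired), collapse = ", "))
  out <- data.frame(participant_id = wide$participant_id,
                    test1 = wide[[paste0(col, "_1")]],
                    test2 = wide[[paste0(col, "_2")]],
                    stringsAsFactors = FALSE)
  out$difference <- out$test2 - out$test1
  out$true_score <- (out$test1 + out$test2) / 2
  class(out) <- c("paired_estimates", "data.frame")
  out
}

#' Full Bayesian test-retest agreement report
#'
#' For each checkpoint and each psychometric parameter (PSE and
#' uncertainty), runs the complete agreement suite on the paired Test 1 /
#' Test 2 estimates: limits of agreement, the Bayesian mean-bias model, the
#' bias-vs-true-score regression, the Test 1 vs Test 2 regression, and
#' ICC(2,1). Optionally fits the movement-direction logistic model on the
#' pooled trial logs. The per-cell good-agreement flag is true when none of
#' the three Bland-Altman posteriors (mean bias, regression intercept,
#' regression slope) has more than 90% of its mass outside its ROPE; the
#' raw ROPE fractions are always reported so other rules can be applied.
#'
#' @param x Sessions in any form accepted by [session_summary()].
#' @param checkpoints Checkpoints to analyse (default 25, 50, 75).
#' @param mcmc An [mcmc_config()].
#' @param trials Optional pooled trial-log data frame (see [trial_log()]);
#'   when supplied (or when `x` carries full sessions) the direction-bias
#'   model is fitted too.
#' @param include_direction_bias Logical; fit the direction-bias model.
#' @return An object of class `"agreement_report"`.
#' @export
agreement_report <- function(x, checkpoints = c(25, 50, 75),
                             mcmc = mcmc_config(), trials = NULL,
                             include_direction_bias = !is.null(trials)) {
  if (is.null(trials) && include_direction_bias) trials <- try_trial_log(x)
  results <- list()
  n <- NA_integer_
  for (cpt in checkpoints) {
    for (param in c("alpha", "beta")) {
      pe <- paired_estimates(x, cpt, param)
      n <- nrow(pe)
      loa <- limits_of_agreement(pe$difference)
      mb <- fit_mean_bias(pe$difference, mcmc)
      br <- fit_bias_regression(pe$true_score, pe$difference, mcmc)
      rr <- fit_retest_regression(pe$test1, pe$test2, mcmc)
      icc <- icc_2_1(pe$test1, pe$test2)
      fracs <- c(mb$mu$rope_fraction, br$intercept$rope_fraction,
                 br$slope$rope_fraction)
      results[[paste(cpt, param, sep = ".")]] <- list(
        checkpoint = cpt, parameter = param, paired = pe, loa = loa,
        mean_bias = mb, bias_regression = br, retest_regression = rr,
        icc = icc, good_agreement = all(fracs >= 0.10))
    }
  }
  direction <- NULL
  if (include_direction_bias && !is.null(trials)) {
    fit <- fit_direction_bias_model(trials, mcmc)
    direction <- list(fit = fit, contrast = direction_contrast(fit))
  }
  structure(list(results = results, direction = direction,
                 checkpoints = checkpoints, n_participants = n, mcmc = mcmc),
            class = "agreement_report")
}

try_trial_log <- function(x) {
  out <- tryCatch(trial_log(x), error = function(e) NULL)
  out
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  cat(sprintf("Test-retest agreement report (%d participants)\n", x$n_participants))
  for (res in x$results) {
    label <- if (res$parameter == "alpha") "PSE (alpha)" else "Uncertainty (beta)"
    cat(sprintf("\n%s, %d trials:\n", label, res$checkpoint))
    cat(sprintf("  Limits of agreement: %.1f to %.1f mm\n", res$loa[1], res$loa[2]))
    cat("  Mean bias: ", format_summary(res$mean_bias$mu, digits), "\n", sep = "")
    cat("  Bias regression slope: ", format_summary(res$bias_regression$slope, digits),
        "\n", sep = "")
    cat("  Bias regression intercept: ",
        format_summary(res$bias_regression$intercept, digits), "\n", sep = "")
    cat("  Test1-Test2 regression slope: ",
        format_summary(res$retest_regression$slope, digits), "\n", sep = "")
    cat("  Test1-Test2 regression intercept: ",
        format_summary(res$retest_regression$intercept, digits), "\n", sep = "")
    cat(sprintf("  ICC(2,1): %.2f [%.2f, %.2f]\n", res$icc$icc, res$icc$ci_low,
                res$icc$ci_high))
    cat(sprintf("  Good agreement: %s\n", if (res$good_agreement) "yes" else "no"))
  }
  if (!is.null(x$direction)) {
    cat("\nMovement-direction analysis:\n  ",
        format_summary(x$direction$contrast, digits), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(res) {
    data.frame(parameter = res$parameter, checkpoint = res$checkpoint,
               n = nrow(res$paired),
               loa_low = res$loa[1], loa_high = res$loa[2],
               mean_bias = res$mean_bias$mu$mean,
               mean_bias_hdi_low = res$mean_bias$mu$hdi_low,
               mean_bias_hdi_high = res$mean_bias$mu$hdi_high,
               mean_bias_rope_pct = 100 * res$mean_bias$mu$rope_fraction,
               bias_slope = res$bias_regression$slope$mean,
               bias_slope_hdi_low = res$bias_regression$slope$hdi_low,
               bias_slope_hdi_high = res$bias_regression$slope$hdi_high,
               bias_slope_rope_pct = 100 * res$bias_regression$slope$rope_fraction,
               bias_intercept = res$bias_regression$intercept$mean,
               bias_intercept_hdi_low = res$bias_regression$intercept$hdi_low,
               bias_intercept_hdi_high = res$bias_regression$intercept$hdi_high,
               bias_intercept_rope_pct = 100 * res$bias_regression$intercept$rope_fraction,
               retest_slope = res$retest_regression$slope$mean,
               retest_slope_hdi_low = res$retest_regression$slope$hdi_low,
               retest_slope_hdi_high = res$retest_regression$slope$hdi_high,
               retest_intercept = res$retest_regression$intercept$mean,
               retest_intercept_hdi_low = res$retest_regression$intercept$hdi_low,
               retest_intercept_hdi_high = res$retest_regression$intercept$hdi_high,
               icc = res$icc$icc, icc_ci_low = res$icc$ci_low,
               icc_ci_high = res$icc$ci_high,
               good_agreement = res$good_agreement,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' @export
plot.agreement_report <- function(x, checkpoint = max(x$checkpoints), ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (param in c("alpha", "beta")) {
    res <- x$results[[paste(checkpoint, param, sep = ".")]]
    if (is.null(res)) next
    pe <- res$paired
    label <- if (param == "alpha") "PSE" else "Uncertainty"
    plot(pe$true_score, pe$difference, pch = 19,
         xlab = sprintf("Mean of tests (%s, mm)", label),
         ylab = "Test 2 - Test 1 (mm)",
         main = sprintf("Bland-Altman: %s, %d trials", label, checkpoint),
         ylim = range(c(pe$difference, res$loa)))
    abline(h = res$loa, lty = 3)
    abline(h = res$mean_bias$mu$mean, lty = 1, col = "steelblue")
    abline(h = 0, lty = 2, col = "grey60")
  }
  invisible(x)
}
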