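# Independent brute-force oracles for the adaptive engine. These share no
# code with the package internals: entropy, the two-branch expected-entropy
# enumeration and the weighted means are written out longhand.

oracle_entropy <- function(p) {
  h <- 0
  for (x in as.numeric(p)) if (x > 0) h <- h - x * log2(x)
  h
}

# p("left" | alpha, beta, s) evaluated directly from the closed form
oracle_left_prob <- function(alpha, beta, s) pnorm((s - alpha) / beta)

# expected entropy at one stimulus by explicit enumeration of both branches
oracle_expected_entropy <- function(mass, alpha, beta, s) {
  lik_left <- outer(alpha, beta, function(a, b) oracle_left_prob(a, b, s))
  eh <- 0
  for (lik in list(lik_left, 1 - lik_left)) {
    u <- mass * lik
    z <- sum(u)
    if (z > 0) eh <- eh + z * oracle_entropy(u / z)
  }
  eh
}

# argmin of expected entropy over all stimuli, smallest stimulus on ties
oracle_select <- function(mass, alpha, beta, stimuli) {
  best_s <- NA_real_
  best_eh <- Inf
  for (s in stimuli) {
    eh <- oracle_expected_entropy(mass, alpha, beta, s)
    if (eh < best_eh - 1e-12) {
      best_eh <- eh
      best_s <- s
    }
  }
  best_s
}

oracle_marginal_means <- function(mass, alpha, beta) {
  ahat <- 0
  bhat <- 0
  for (i in seq_along(alpha)) for (j in seq_along(beta)) {
    ahat <- ahat + mass[i, j] * alpha[i]
    bhat <- bhat + mass[i, j] * beta[j]
  }
  c(ahat, bhat)
}

# random coarse engine state: symmetric alpha grid, positive beta grid,
# Dirichlet-ish random mass
random_engine_state <- function(n_alpha_half = 6, n_beta = 8) {
  half <- sort(runif(n_alpha_half, 1, 100))
  alpha <- c(-rev(half), 0, half)
  beta <- sort(runif(n_beta, 0.5, 60))
  mass <- matrix(rexp(length(alpha) * length(beta)), length(alpha), length(beta))
  mass <- mass / sum(mass)
  grid <- parameter_grid(alpha, beta)
  list(grid = grid, mass = mass,
       posterior = structure(list(grid = grid, mass = mass),
                             class = "psi_posterior"))
}

# reduced sampler settings for unit tests
fast_mcmc <- function(seed = 1) mcmc_config(draws = 2000, chains = 2, tuning = 1000,
                                            seed = seed)
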