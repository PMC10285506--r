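Package: psiprop
Title: Adaptive Bayesian Assessment of Lower Limb Position Sense
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the point of subjective equality (PSE) and
    uncertainty of standing lower limb position sense with a two-alternative
    forced choice (2AFC) task driven by the Psi adaptive algorithm. Provides
    the grid-based Bayesian engine (entropy-minimising stimulus selection,
    trial-by-trial posterior updates, marginal-mean estimates), the 75-trial
    treadmill protocol with pseudorandomised movement directions and
    preselected engagement stimuli, simulated 2AFC observers for validation
    studies, and a Bayesian test-retest agreement suite (Bland-Altman mean
    bias and bias regression with ROPE/HDI summaries, limits of agreement,
    test-retest regression, and ICC(2,1)) fitted by MCMC through JAGS.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    lme4,
    withr
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
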