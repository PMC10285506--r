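---
title: "Methods: adaptive Bayesian assessment of lower limb position sense"
author: "psiprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive Bayesian assessment of lower limb position sense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Standing lower limb position sense can be characterised with a
two-alternative forced choice (2AFC) task: one foot (the reference) stays
fixed while a treadmill belt passively moves the other (test) foot to a
stimulus position, and the participant judges which foot is more forward.
All positions are expressed as *foot position difference* — the left minus
right ankle-marker position along the walking axis, in millimetres, so
positive values mean the left foot is ahead.

Two parameters summarise the sense: the **point of subjective equality**
(PSE, `alpha`), the foot position difference the participant perceives as
"feet aligned", and the **uncertainty** (`beta`), the spread of the
judgement noise. `psiprop` implements the full measurement pipeline — the
adaptive engine that estimates these parameters efficiently, the trial
protocol around it, simulated observers for validation, and the Bayesian
test–retest agreement analysis.

## Psychometric model

The probability of judging "left foot forward" at stimulus $s$ is a pure
two-parameter normal CDF,

$$\psi(s) = \Phi\!\left(\frac{s - \alpha}{\beta}\right),$$

with no lapse or guess parameters: at the extreme stimuli ($\pm 100$ mm)
responses are effectively deterministic for realistic parameter values, so
the extra parameters would add nothing but variance. `response_probability()`
evaluates the model and `likelihood_tables()` pre-tabulates
$p(r \mid \alpha, \beta, s)$ for both responses over the whole parameter
grid and all 21 stimulus locations, so the engine indexes rather than
recomputes.

## The adaptive (Psi-style) engine

The engine maintains a discrete joint posterior over $(\alpha, \beta)$.

**Parameter grid.** `alpha` from $-100$ to $+100$ mm in 1 mm steps (201
values) and `beta` from 0.5 to 150 mm in 0.5 mm steps (300 values). The
grid is a package choice: the `alpha` range covers the full stimulus range
at sub-stimulus resolution, and the `beta` range extends far enough that
the truncated exponential prior keeps its mean within about 0.2 mm of its
nominal value. Both are exposed through `parameter_grid()`.

**Priors.** $\alpha \sim N(0, 20)$ mm and
$\beta \sim \text{Exponential}(\text{mean } 20)$ mm, independent —
wide, maximum-entropy-style choices on the scale of the task. They are
discretised by evaluating the densities at the grid points and
renormalising (not by bin integration); at this resolution the difference
is negligible, and the resulting marginal moments (`alpha` SD 20.00 mm,
`beta` mean 20.17 mm on the default grid) are recomputed by
`scripts/acceptance.R`.

**Stimulus selection.** Before each trial the engine computes, for every
candidate stimulus, the expected entropy (in bits, $0\log 0 := 0$) of the
posterior after one hypothetical trial, averaging the "left" and "right"
branches weighted by their predictive probabilities, and presents the
stimulus minimising it. Exact ties — which arise only in degenerate states
such as a point-mass posterior — go deterministically to the smallest
stimulus value so that runs are exactly reproducible; numerically, ties are
resolved within $10^{-12}$ bits. The per-trial scan is implemented in
compiled code; `expected_entropy()` exposes the plain single-stimulus
computation.

**Updating and estimates.** Every response — including responses to the
preselected engagement stimuli below — updates the posterior by Bayes'
rule, since all responses are informative and the updates commute. Cells
keep their computed mass (no flooring); renormalisation divides by the
summed mass. Running estimates are the marginal means of `alpha` and
`beta`.

```{r}
library(psiprop)
post <- init_posterior()
tab <- likelihood_tables()
select_stimulus(post, tab)          # first stimulus chosen from the prior
post <- update_posterior(post, tab, 0, "left")
marginal_estimates(post)
```

## Trial protocol

`run_session()` executes the 75-trial session:

- **Movement directions.** 38 trials start with the test foot in front of
  the stimulus (moving backward) and 37 behind (moving forward), in seeded
  random order. Balancing directions washes out any direction-linked
  response bias; general trial counts split `ceiling(n/2)` / `floor(n/2)`.
- **Start positions.** Drawn from $N(\mp 100, 5)$ mm (forward / backward),
  rejection-sampled until the draw lies on the correct side of the
  stimulus. The acceptance probability is at least one half for every grid
  stimulus, so the cap of 1000 draws only trips on misconfiguration.
- **Preselected stimuli.** To keep participants engaged, one *far*
  stimulus ($\pm 90$ or $\pm 100$ mm, uniform) is inserted per complete
  10-trial block and one *near* stimulus (current PSE estimate
  $\pm 10/20/30$ mm, uniform among the six offsets, snapped to the nearest
  grid location, which also clips it to $\pm 100$) per complete 5-trial
  block; none within the first five trials. "Once every 10 (5) trials" is
  operationalised as one uniform placement per complete consecutive block:
  with 75 trials the trailing 71–75 block is a complete 5-block (near
  insertion) but not a complete 10-block (no far insertion), giving exactly
  7 far and 14 near trials. When a near draw collides with a far trial it
  is re-placed within its block. Near placement uses the engine's current
  PSE estimate as-is (no baseline correction inside the loop).
- **Baseline correction.** `baseline_offset()` rounds the residual
  left–right marker difference to the nearest millimetre, half away from
  zero; it is recorded as session metadata and applied when interpreting
  marker-based recordings. Belt speeds and rest breaks are metadata only.
- **Checkpoints.** Estimates are recorded after trials 25, 50 and 75 (and
  always after the final trial for shorter sessions), enabling the
  "is 50 trials enough?" comparison downstream.

## Simulated observers and cohorts

`observer_spec()` defines a stationary 2AFC responder following the normal
CDF above, optionally with a movement-direction bias: the effective PSE is
shifted $\pm\delta/2$ on backward/forward trials. The shift is
parameterised in millimetres (rather than as a logit offset) so the
injected confound lives in stimulus units; $\delta = 0$ is the validated
case and $\delta = 40$ mm serves as the power check.

`simulate_cohort()` draws each participant's true parameters from
$\alpha \sim N(12, 16)$ mm and $\beta \sim N^{+}(18, 7)$ mm
(truncated positive) and runs the full protocol twice. The population
means are the young-adult group scale; the SDs are back-derived from the
spread implied by reported group-level credible intervals
($\text{half-width}/1.96 \times \sqrt{13}$). Optional drift parameters
shift the truth between tests; the default is none, which is the
appropriate null for agreement validation. The generator emulates
stationary, memoryless responders — it does **not** model lapses, fatigue
drift within a session, postural sway or memory effects, so passing
validation says the *pipeline* is unbiased and calibrated under the stated
population, not that human data are free of those effects.

## Agreement analysis

`agreement_report()` runs, per checkpoint and per parameter (PSE,
uncertainty), on the paired Test 1/Test 2 estimates:

1. **Limits of agreement**: mean difference $\pm 1.96 \times$ sample SD
   ($n-1$ denominator). Differences are oriented **Test 2 − Test 1**
   throughout.
2. **Mean bias** (`fit_mean_bias`): differences $\sim N(\mu, \sigma)$,
   ROPE $\pm 5$ mm on $\mu$.
3. **Bias regression** (`fit_bias_regression`): difference regressed on
   the "true score" proxy (mean of the two tests); ROPEs $\pm 5$ mm
   (intercept) and $\pm 0.1$ (slope — 1 mm of bias per 10 mm of true
   score).
4. **Retest regression** (`fit_retest_regression`): Test 2 on Test 1; no
   ROPE, the HDIs characterise how plausible slope 1 / intercept 0 is.
5. **ICC(2,1)**: two-way random-effects, absolute-agreement,
   single-measures ICC from the ANOVA mean squares, with the standard
   F-based (Shrout–Fleiss / McGraw–Wong) 95% CI.

The **movement-direction model** (`fit_direction_bias_model`) is a
Bernoulli logistic regression over all trials of all participants (both
tests pooled): an intercept per participant, one coefficient per movement
direction and a common stimulus slope. The direction contrast
(backward − forward) is summarised on the coefficient (logit) scale with a
ROPE of $\pm 0.5$ — the scale on which that ROPE is meaningful, which we
prefer over a probability-scale contrast.

**Sampling.** All four models are fit by MCMC through JAGS: by default
10,000 retained draws in each of 4 chains after 2,000 adaptation
iterations per chain, with seeded chain RNGs for bit-reproducibility.
Convergence is reported via split-chain R-hat and effective sample size.
Because the logistic model's per-participant intercepts and direction
coefficients are only weakly identified individually (a constant can move
between them), diagnostics are computed on the identified combinations —
participant intercept plus mean direction effect, the direction contrast,
and the slope.

**Priors for the analysis models** are weakly informative and scaled to
the data: Normal(0, 10 × data SD) for location and regression
coefficients (slope priors scaled by the predictor SD), Exponential(mean
= data SD) for residual scales, and Normal(0, 5) on the logit scale for
the logistic model's coefficients. The residual scale is floored at
$10^{-6}$ of the data scale so that degenerate (noise-free) inputs remain
well-posed.

**Good agreement** is flagged per cell when none of the three
Bland-Altman posteriors (mean bias, bias-regression intercept and slope)
has more than 90% of its mass outside its ROPE. This is one defensible
reading of a "90% of the posteriors" rule; the raw ROPE fractions are
always reported so users can apply stricter ones.

## Numerical and design notes

- Entropy uses base-2 logarithms (bits) with $0\log 0 := 0$.
- Posterior mass is conserved to $10^{-9}$ by every engine operation
  (tested); updates are order-free to $10^{-12}$.
- The HDI is the narrowest window of the sorted draws containing
  $\lceil 0.95\, n\rceil$ of them; ROPE fractions count draws inclusively.
- `icc_2_1()` flags degenerate variance (zero error mean square) instead
  of failing; the point estimate is still returned.
- Config files are YAML (`read_run_config()`); command-line flags
  override file values. The `psiprop` script in `exec/` exposes
  `simulate-session`, `simulate-cohort`, `analyze-agreement` and `replay`.
- `replay_trial_log()` re-runs the engine on a logged session and matches
  the logged trajectory to $10^{-9}$ mm when the grids match — a cheap
  integrity check for archived data.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to balance
Monte-Carlo resolution against runtime: 1,000 random posteriors for the
stimulus-selection oracle (coarse random grids, plus spot checks on the
full default grid); 200 simulated 75-trial sessions at true
$(\alpha, \beta) = (12, 18)$ mm for parameter recovery (mean PSE error
within 2 mm, mean uncertainty error within 3 mm, with the 50-trial
checkpoint close behind); 20 replicate 13-participant null cohorts for
direction-contrast calibration; and reduced sampler settings
(2 chains × 1,000–2,000 draws) wherever a posterior mean rather than a
tail quantity is asserted.

## Limitations

The package analyses sagittal-plane foot position difference only; it does
not drive hardware, enforce rest breaks, or model three-dimensional
position sense. The simulator's stationarity means test–retest variability
in simulated cohorts comes only from response noise and the adaptive
procedure itself — real cohorts add physiological drift, which is exactly
what the agreement analysis is designed to detect.
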