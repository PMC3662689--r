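---
title: "Measuring the internal model of motor error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the internal model of motor error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorlottery)
```

## The question and the model

Skilled reaching is stochastic: endpoints scatter around the aim point. A
decision maker who plans movements optimally needs an *internal model* of
that scatter. This package implements an analysis that asks, subject by
subject, whether the internal model implicit in target choices matches the
true endpoint distribution — in **variance** and in **anisotropy**.

The true distribution is taken to be a centered bivariate Gaussian. We
parameterize it by the geometric-mean variance and the axis ratio,

- σ² = σ_h · σ_v (mm²), the *variance parameter*,
- η = σ_v / σ_h, the *anisotropy parameter* (η = 1 is isotropic),

so σ_h² = σ²/η and σ_v² = σ²·η. This convention makes η = 1 exactly the
isotropic case and puts the fitted internal parameters (σ̃², η̃) on the same
scale as the true ones, so ratios σ̃²/σ² and η̃/η read directly as
"overestimates variance", "underestimates elongation". The per-axis
correlation ρ is estimated but not propagated into the choice model: for the
rectangle sizes used here its effect on hit probability is bounded by a few
percentage points (`correlation_sensitivity()` verifies this per dataset),
and circles are rotation invariant.

Hit probabilities are Gaussian masses over the target region. With
uncorrelated axes the rectangle mass is a product of normal CDF differences;
the circle mass is a one-dimensional chord integral. The **equivalent
radius** of a rectangle under an internal model is the circle radius with
equal assumed hit probability. Because a circle packs its area where a
Gaussian's density is highest, the equivalent radius of an equal-area
rectangle is *smaller* than the area radius √(wh/π) at any finite variance,
and converges to it as σ̃² → ∞. That limit *is* the area-matching chooser,
which is why area matching is a nested special case of the Gaussian model.

## Measuring equivalent radii

Choices are collected by transformed up-down staircases on the circle
radius (multiplicative steps; log₁₀ step sizes shrink over the first three
reversals). The response model is a Quick–Weibull psychometric function of
radius,

P(choose circle | r) = 1 − exp(−(r/a_j)^γ),

with one position a_j per rectangle and a single steepness γ shared across
rectangles — the shared γ stabilizes the fit at staircase sample sizes and
doubles as a choice-consistency index. The point of subjective equality is
r_eq = a·(ln 2)^(1/γ), which uses both estimates. Fitting is by joint
Bernoulli maximum likelihood on log parameters (positivity is structural),
with analytic gradients and five steepness starts; perfectly separable data
are flagged and the steepness pinned at 50.

Two design decisions here were genuinely open:

- **Staircase orientation and start.** "Up" enlarges the circle (triggered
  by "rectangle easier" runs), so a 1-up/2-down track converges near the
  70.7% choose-circle point. Starting radii are the area-equivalent radius
  of the paired rectangle — an anchor that favors neither the Gaussian nor
  the area-matching hypothesis.
- **Log base.** Step sizes are interpreted as log₁₀ units, the
  psychophysics convention; both the schedule and the base are configurable.

## Inverting radii to the internal model

Measured log radii are modeled as the internal model's predicted log
equivalent radii plus Gaussian noise (SD σ_e). The Gaussian fit maximizes
the profile likelihood over (σ̃², η̃) — σ_e has a closed-form profile — with
a coarse grid (σ̃² over 0.1–1000× the squared mean measured radius, η̃ over
0.25–4) followed by Nelder–Mead refinement of the log parameters. The
area-matching fit is closed form. Numerical guards, all of which matter in
practice:

- σ_e is floored at 10⁻⁶ log-units so a zero-residual fit keeps a finite
  likelihood without disturbing the classification order;
- σ̃² is clamped to a wide box (10⁻⁴–10⁸ × scale) whose upper end is
  numerically indistinguishable from the area-matching limit, so "blown-up"
  variance estimates terminate cleanly instead of drifting;
- the equivalent-radius map is solved by a safeguarded Newton iteration on
  log r (bracketing bisection fallback), vectorized across rectangles, with
  Gauss–Legendre quadrature after a trigonometric substitution that removes
  the chord-integral endpoint singularity. Agreement with adaptive
  quadrature and Monte-Carlo oracles is checked in the test suite.

Classification uses the likelihood-ratio statistic λ = 2(logL_G − logL_A)
against the 95th percentile of χ² with **2 degrees of freedom** (Gaussian:
σ̃², η̃, σ_e; area matching: σ_e). Parameter counting fixes df = 2. One
caveat is stated rather than hidden: the area-matching null sits at the
σ̃² → ∞ boundary of the Gaussian family, where the χ² asymptotics are not
guaranteed. We therefore calibrate the test empirically — under
area-matching generators the test suite checks that the "gaussian" label
rate stays near the nominal 5%.

Confidence intervals come from parametric-bootstrap *virtual experiments*:
endpoints are resampled nonparametrically from the non-timeout reaches, the
staircases are re-run with their original adaptive logic against responses
drawn from the fitted psychometric curves, and the entire fitting chain is
repeated. We re-run the staircases adaptively (rather than replaying the
original radius sequences) because the staircase is part of the measurement
process the bootstrap is meant to propagate. Intervals are 2.5/97.5
percentiles of σ̃²/σ² and η̃/η.

## Motor lotteries and efficiency

The expected-gain module scores aim points on a landscape of one reward and
one penalty circle (equal radii, centers on a horizontal axis; landing in
the overlap accrues both payoffs). The default six conditions are reward
+100, penalty −100 or −500, radius 8.97 mm, center distance 1, 1.5 or 2
radii. The optimum lies on the symmetry axis; it is found by a 0.05 mm scan
refined by golden-section search to 0.001 mm, with plateau ties (possible
under the uniform-disk model) broken toward the reward-circle center.

**Efficiency** of an internal model is the true expected gain at the
model-optimal aim divided by the maximum true expected gain. Across
conditions we report the *mean of per-condition ratios* by default; the
ratio of summed gains is available via `aggregate = "ratio_of_means"`. The
choice matters: with true SD 4.05 mm, a chooser assuming 4× her true
variance reaches 70.0% (mean of ratios) or 75.6% (ratio of means). The
discrepancy is concentrated in the penalty −500, distance-1R condition,
where the erroneous model's gain surface is nearly flat over several mm
while the true gain varies steeply, so the "efficiency of an erroneous
chooser" is intrinsically sensitive to how the near-flat optimum is
resolved. We report the exact argmax under mean-of-ratios.

The uniform-disk chooser of the introductory simulation "knows her SD":
a uniform disk of radius R has per-axis SD R/2, so a subject with true SD
4.05 mm assumes R = 8.1 mm.

## What the synthetic-data generator does and does not emulate

`subject_spec()` generates endpoints from the assumed bivariate Gaussian
(defaults σ_h = 4 mm, σ_v = 5.76 mm — axis ratio 1.44, the typical
empirical value — ρ = 0, 5% timeouts) and choices from a configurable
internal model passed through the same Weibull family used for fitting,
positioned so its point of subjective equality equals the internal model's
equivalent radius. That self-consistency is deliberate: it makes parameter
recovery a meaningful test of the estimation chain. Default steepness
γ_choice = 4 corresponds to a moderately consistent chooser.

Consequences to keep in mind:

- Passing recovery tests shows the *estimation chain* is correct and
  calibrated under the assumed generative process. It cannot show that real
  choosers follow a Weibull decision link, have lapse-free responses (no
  lapse parameter is generated or fitted — none is reported for this
  paradigm), or hold a Gaussian internal model at all.
- Endpoint non-Gaussianity, sequential dependencies, learning and fatigue
  are not simulated; the Q-Q linearity check (`qq_linearity()`) is the
  package's only defense against the first.
- Timeouts are independent coin flips carrying no endpoint, mirroring the
  exclusion rule used in analysis.

## Simulation scales used by the test suite

Fixed seeds throughout; sizes are the package's own choices, balancing
Monte-Carlo error against desk-scale runtimes. Quadrature checks use
10⁶–10⁷-draw Monte-Carlo oracles (3 standard-error bands). Staircase
tracking points use 300–500 runs per rule. The nested bootstrap-coverage
study runs 80 outer subjects × 100 bootstrap replicates under the second
shipped design (8 rectangles, one 60-trial 1-up/1-down staircase each);
coverage of the 95% intervals is required to fall in 93–97%. The staircase
trial count matters here: at appreciably smaller designs (≈240 choice
trials) the shared steepness is overestimated enough (~20%) that the
parametric bootstrap resamples too little response noise and the intervals
run a few points narrow. Type-I calibration of the nested test uses 1000
radius-level area-matching subjects with residual SD 0.05 log-units.
End-to-end classification checks use 100 seeds per generator type.

## Known limitations

- The χ² reference for the nested test is asymptotic and boundary-adjacent
  (see above); the empirical calibration is the real evidence.
- Percentile intervals at 100 bootstrap replicates estimate tail quantiles
  noisily; final analyses should use 1000 replicates (the default of
  `bootstrap_cis()`).
- The parametric bootstrap is mildly anticonservative at staircase sample
  sizes: the shared-steepness MLE is biased steep in finite samples (~9% at
  480 trials), so resampled responses carry slightly too little decision
  noise and the 95% intervals cover a few points below nominal (~91% in our
  nested simulation at the smaller shipped design). The bias, and with it
  the shortfall, shrinks with trial count; it is a property of the
  measurement model itself, not of the resampling implementation.
- The uniform-disk expected-gain surface is piecewise smooth; its optimum
  can sit on a plateau and is resolved by the tie-break rule, not by the
  data.
- Anisotropy becomes unidentifiable as σ̃² grows — predicted equivalent
  radii for different η̃ converge — so η̃ is not interpreted for
  area-matching-type subjects.
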