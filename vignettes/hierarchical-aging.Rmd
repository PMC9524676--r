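---
title: "Hierarchical process models of behavioral aging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical process models of behavioral aging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormspan)
```

## The scientific question

In long-lived cohorts followed continuously — the motivating case is
*C. elegans* lifespan experiments scored by automated imaging — each
individual passes through a stereotyped sequence of behavioral states:
vigorous movement, weak movement, a non-moving-but-alive period, and death.
The age at vigorous movement cessation (VMC) is a behavioral biomarker of
aging, and two summaries of its relation to lifespan have circulated: a
*proportional* description ("individuals spend a fixed fraction of life
moving vigorously") and an *additive* one ("death follows VMC by a fixed
interval").  The two make different predictions about the joint
distribution of VMC and death times and about how an individual's
remaining lifespan after VMC depends on *when* VMC occurred.

wormspan packages the statistical machinery needed to ask these questions
of an event table — per-individual VMC, WMC and death times with group and
batch labels — and the stochastic process models that interpret the
answers.  The central modelling idea is *hierarchical*: VMC and death may
be set by two distinct stochastic declines whose average rates co-vary
because both depend on a shared upstream factor.  Such a system generically
produces the joint signature seen in worm data: VMC and death times
correlate positively across individuals, yet the regression slope of death
time on VMC time is below one, equivalently remaining lifespan *decreases*
with VMC age.

## The decline simulators

Each simulated individual is a discrete-time biased random walk
\(W(t+\Delta t) - W(t) \sim N(-\mu\,\Delta t,\ \sigma^2 \Delta t)\)
started at displacement \(x_0\) and absorbed at fixed thresholds; the
first step at which the walk sits below a threshold is the event time.
Crossing \(\theta_1\) is the VMC analog and crossing \(\theta_2 <
\theta_1\) the death analog.  `wiener_config()` holds the full
parameterization; `aging_model()` names the canonical variants:

| variant | architecture | signature (death~VMC slope, remaining~VMC slope) |
|---|---|---|
| `single` | one walk, two thresholds | slope ≈ 1, remaining ≈ 0 |
| `single_frailty` | one walk, gamma-distributed rates | slope > 1, remaining > 0 |
| `flip` | rate inversion at VMC | slope < 1, remaining < 0 |
| `two_indep` | two independent walks | correlation ≈ 0 |
| `two_shared` | two walks, shared frailty | slope in (0,1), remaining < 0, correlation > 0 |

The `single` case is the strong Markov property made visible: conditional
on reaching \(\theta_1\), the future of the walk is independent of how
long it took to get there, so the time from VMC to death is independent of
the VMC age.  Only the hierarchical `two_shared` architecture reproduces
all three features of the empirical pattern at once, which is the
scientific argument the simulators exist to support.

Default parameter scales.  Defaults put the starting displacement at
\(4\times10^5\) times the mean decline rate (`x0_factor = 4e5`,
`drift_mean = 1`), with the VMC threshold halfway down and death at the
origin, and 1000 walkers.  The step `dt = 100` makes the deterministic
death crossing take 4000 steps (the VMC crossing 2000), comfortably above
the thousand-step floor that keeps discretization error in the
first-passage times negligible relative to their spread; `max_steps`
defaults to twenty times the deterministic crossing, and walkers still
unabsorbed there are right-censored.  `noise_var = 4000` gives the
single-process VMC times a coefficient of variation of about 0.14,
a realistic dispersion for an isogenic cohort.

Frailty.  Population heterogeneity multiplies each individual's drift by a
unit-mean gamma variate with shape \(k\) (variance \(1/k\)), so rates stay
centered on the population mean and heterogeneity strength is the single
knob \(1/\sqrt{k}\) (the rate CV).  The single-process frailty variants
default to \(k = 1/0.3^2 \approx 11.1\) (CV 0.3, a moderate heterogeneity
consistent with the dispersion of isogenic-cohort lifespans); the
`flip` variant replaces each individual's drift by
\(\mu^2/\mu_i\) at the moment of VMC — the harmonic reflection about the
mean, the simplest rule that exactly inverts the ordering of relative
rates while preserving the population center.

The shared-frailty two-process preset uses \(k = 4\) with `noise_var =
2.5e5` and the VMC threshold at \(0.64\,x_0\).  These values are chosen
together, because the slope of death on VMC in this architecture is a
variance ratio: writing \(f\) for the frailty-induced variance of VMC
times and \(n_1\) for their first-passage noise variance, the slope is
\((d_2/d_1)\,f/(f + n_1)\) with \(d_j\) the threshold distances.  It
falls below one only when the passage-time noise exceeds the
frailty-induced spread scaled by the threshold geometry.  The preset sits
in that regime and yields slope, remaining-lifespan slope and correlation
of the same sign and comparable magnitude to empirical cohorts.  A side
effect of genuinely independent walks is that roughly a third of
individuals have their death walk cross before their VMC walk; these rows
are retained and flagged in the `order_reversed` column (set
`drop_reversed = TRUE` to discard them), since dropping them would
truncate the joint distribution that the regressions are meant to see.

Coupling.  For tunable dependence, the per-step increments of the two
walks share a common noise component of weight \(w\):
increment \(= N(-\mu\,dt, (1-w)\sigma^2 dt) + N(0, w\sigma^2 dt)\), the
second term common to both walks.  Means and total variances are
independent of \(w\) while the increment correlation is exactly \(w\), so
the sweep from \(w = 0\) to \(1\) moves the model continuously from fully
independent to fully coupled without changing the marginals.  A literal
prefixed form \((1-w)N(-\mu dt,(1-w)\sigma^2 dt) + wN(0,w\sigma^2 dt)\),
whose moments do depend on \(w\), is available behind
`literal_coupling = TRUE` for comparison.  `sweep_coupling()` runs without
frailty by default so its \(w = 0\) endpoint coincides with the
independent two-process model, and seeds run \(i\) with `seed + i - 1`.

## The cohort emulator

`generate_cohort()` produces empirical-style tables (hours since the first
day of adulthood) with known ground truth for exercising the regression
and AFT stages: per individual, a unit-mean gamma frailty divides both the
vigorous span (reference mean 230 h) and the post-VMC span (130 h), each
with lognormal noise of CV 0.15; group fold-changes and batch scale
factors then multiply the times.  Because effects are exactly
multiplicative on identically distributed baselines, the log event times
follow an exact location-shift model, so the AFT coefficients have a known
truth to recover.  WMC is placed a Beta(9,1) fraction of the way from VMC
to death, which makes the non-moving state a few percent of life, as in
real cohorts.  Right-censoring marks exactly `floor(censor_frac * n)`
randomly chosen individuals, censored uniformly between WMC and death.

What the emulator does *not* reproduce: measurement error in event calls,
informative censoring, batch-by-group interactions, non-multiplicative
(crossing-hazard) intervention effects, and the discreteness of
hour-resolution scoring.  Tests passing on emulated cohorts therefore
validate the estimators under the AFT data-generating assumptions, not the
robustness of those assumptions to real-world violations.

## Hazard estimation

`cumulative_hazard()` implements the Nelson–Aalen estimator
\(\hat H(t) = \sum_{t_j \le t} d_j/n_j\) with ties aggregated; the
\(-\log\) Kaplan–Meier variant is available via `type = "km"` for fidelity
to analyses phrased that way (the two agree asymptotically; the
Nelson–Aalen increments differentiate more stably).  `hazard_rate()`
smooths the increments with an Epanechnikov kernel.  Defaults: a 200-point
grid between the 1st and 99th percentiles of event times (the hazard
outside, where too few events accrue, is reported as unestimated rather
than extrapolated) and bandwidth equal to one twentieth of the event-time
range.  The smoother is a deliberate choice that must be stated rather
than assumed: different differentiation schemes change the pointwise
hazard but not the qualitative features (rise, deceleration, fold
changes over multi-day windows) the analyses rest on; sensitivity to
bandwidth should be reported alongside any quantitative hazard ratio,
e.g. via `hazard_fold_change()` at several bandwidths.

Clock-reset hazards (`clock_reset_hazard()`) subtract each individual's
milestone age from its death age and estimate the hazard on durations.
Under a single memoryless decline the clock-reset curve is the same
whatever the milestone age (the strong Markov property again); under
fixed heterogeneity the chronological curve decelerates late in life as
frail individuals are culled, while the clock-reset curve decelerates
less — the contrast the two estimators exist to expose.

## Parametric families

Four censored-MLE families (`fit_parametric()`): Gompertz
\(h = ab\,e^{bt}\); Weibull \(h = (\alpha/\beta)(t/\beta)^{\alpha-1}\);
Weibull with unit-mean gamma frailty of variance \(\sigma^2\) acting
multiplicatively on the hazard, giving the population hazard
\(h_0(t)/(1+\sigma^2 H_0(t))\); and the Inverse Gaussian first-passage
law with survival
\(S(t) = \Phi(\sqrt{\lambda/t}(1 - t/\mu)) - e^{2\lambda/\mu}
\Phi(-\sqrt{\lambda/t}(1 + t/\mu))\), where both \(\Phi\) are the standard
normal CDF — the standard parameterization of the IG survival; a printed
source that ends this formula in a lowercase \(\phi\) is read as the CDF,
since the density there does not yield a valid survival function.  The
log-likelihood is \(\sum_{\text{uncens}} \log h + \sum_{\text{all}} \log
S\), evaluated in log space throughout (`pnorm(log.p = TRUE)`,
`log1p`-style complements) so extreme times underflow gracefully.

Optimization is BFGS on log-parameters (positivity for free) from five
moment/quantile-based starts with a \(10^{-12}\) relative tolerance,
keeping the best converged optimum; the covariance of estimates is the
inverse Hessian mapped through the delta method.  The frailty
\(\sigma = 0\) boundary is allowed, where the family collapses exactly to
Weibull; likelihood-ratio comparisons against that boundary null are
conservative in the usual 50:50 mixture sense.

## Regression of lifespan on VMC age

`fit_vmc_regression()` fits, by Huber M-estimation (`MASS::rlm`, tuning
constant at its standard value, tolerance \(10^{-8}\); `robust = FALSE`
for OLS), one of:

* **additive** — death time on VMC time with batch dummies; with several
  groups present the group main effect and group-by-batch interaction are
  included, a full-rank parameterization of the batch-interaction
  adjustment (`rlm` refuses rank-deficient designs);
* **proportional** — zero-intercept fit with per-batch slope offsets,
  the operational form of "the vigorous span is a fraction of life";
* **remaining** — remaining lifespan \(d - v\) on \(v\); in the
  single-batch OLS configuration its slope equals the additive slope minus
  one exactly, a useful internal consistency check.

The additive-versus-proportional comparison is made through the residuals:
whichever description is wrong leaves squared residuals that depend on
\(v\), quantified by the White statistic \(nR^2\) from regressing squared
residuals on \(v\) and \(v^2\).  Partial \(R^2\) for the VMC term compares
the full model with the batch-only reduction,
\((SSE_r - SSE_f)/SSE_r\), computed at the full fit's final robust
weights so the comparison is between nested fits under one weighting (this
also guarantees the value lands in \([0,1]\)).

Bootstrap inference (`bootstrap_slope()`) resamples individuals within
batch (keeping the design balanced), refits, and reports percentile
intervals; default \(B = 2000\).  Tail probabilities smaller than the
\(1/B\) counting resolution are reported from a normal approximation to
the bootstrap distribution and flagged approximate — a counted bootstrap
p-value can never honestly be \(10^{-10}\).

`segmented_fit()` provides continuous piecewise-linear least squares with
fixed or grid-searched breakpoints (candidate breakpoints at deciles of
the dose range, at least two points per segment) for tri-phasic
dose-response shapes.

## Intervention effects and their decomposition

`fit_aft()` fits \(\log y_i = \beta_X X_i + \beta_R R_i\) per endpoint
(VMC, death, or remaining lifespan) via the censored AFT likelihood with a
lognormal error family by default — chosen because with no censoring it
coincides with least squares on log times, the natural estimator for
fully observed cohorts; a Weibull-AFT family is a flag away.  The
reference group is always explicit, never inferred from label order.
Intervals come from a group-by-batch stratified case bootstrap.

An intervention moving VMC times by \(\beta_{vmc}\) and death times by
\(\beta_{death}\) is summarized by
\[\Delta\mu_s = \tfrac{1}{2}(\log\beta_{vmc} + \log\beta_{death}),
\qquad R_f = \beta_{death}/\beta_{vmc},\]
the shared (proportional) log-shift and the disproportionality ratio.
This geometric-mean parameterization is one of several possible
conventions; it is the package's documented choice, made because it is
symmetric in the two endpoints and exactly invertible
(\(\log\beta_{vmc,death} = \Delta\mu_s \mp \tfrac12\log R_f\)), and it is
isolated in `decompose_effects()` / `reconstruct_effects()` so an
alternative convention is a one-function change.  CIs are propagated
through paired bootstrap replicates — pairing is what makes the interval
honest, since the same resampled individuals must underlie both
endpoints' draws; fitting both endpoints with the same seed on the same
table achieves this.  `dose_response_profile()` orders per-dose effects
and flags dose regimes where \(R_f\) is flat while \(\Delta\mu_s\) moves,
the signature of action on a factor upstream of both processes.

## Numerical choices and degenerate inputs

* Event-time ties (expected at hour resolution) aggregate within
  Nelson–Aalen increments; the KM variant caps the final increment where
  the risk set is exhausted.
* Exact fits (zero residual scale) are returned from OLS directly, where
  the Huber iteration is undefined and coincides with OLS anyway.
* Degenerate bootstrap resamples (zero VMC variance) are redrawn, counted
  and warned about; an all-identical input errors up front.
* The White auxiliary regression drops collinear columns with a warning
  and adjusts its degrees of freedom.
* `simulate()`-style generators: Gompertz by inversion of the cumulative
  hazard, Weibull-frailty by conditional inversion given the gamma draw,
  Inverse Gaussian by the Michael–Schucany–Haas transform.
* All simulators consume one seed recorded in the output metadata;
  identical configuration and seed reproduce tables bit-for-bit.

## Problem sizes

The package's own validation runs at sizes chosen to make sampling noise
small relative to the assertions being checked while keeping a full run
in minutes on one core: sign-taxonomy runs at 5000 walkers per variant;
the first-passage law check at 2000 (where the Kolmogorov–Smirnov test
would detect a 3% CDF distortion); parametric recovery at 50 replicates
of n = 1000; White-test calibration at 1000 replicates of n = 500;
AFT coverage at 100 cohorts of 500 per group with 200 bootstrap
resamples.  `scripts/acceptance.R` re-runs exactly these computations
from scratch and writes the resulting numbers as JSON.

## Known limitations

* The simulators monitor the walk at discrete steps, so crossing times
  carry an \(O(\Delta t)\) lateness plus a boundary-overshoot bias of
  order \(0.58\,\sigma\sqrt{\Delta t}/\mu\); at the default scales this
  is a fraction of a percent of the mean passage time, visible only at
  sample sizes far beyond those used here.
* The hierarchical preset's frailty/noise regime implies many
  order-reversed walker pairs (see above); analyses that treat the two
  walks as literal physiology should use weaker frailty or interpret the
  flagged rows explicitly.
* `weibull_frailty` near \(\sigma = 0\) has a boundary-flat likelihood;
  the convergence flag should be checked before interpreting
  \(\hat\sigma\).
* No competing risks, interval censoring, time-varying covariates or
  covariate-dependent parametric regression; the AFT stage assumes
  multiplicative, time-constant effects.
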