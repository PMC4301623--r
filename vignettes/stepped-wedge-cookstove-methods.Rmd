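---
title: "Models and methods for stepped-wedge cookstove trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for stepped-wedge cookstove trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stovesim)
```

## The scientific setting

Household air pollution from open biomass burning is a major risk factor for
acute lower respiratory infection (ALRI) in young children and for low
birthweight. `stovesim` provides the complete computational machinery for a
community-randomized cookstove trial with a *modified stepped-wedge* rollout:
all clusters start unexposed, one randomization group per month receives the
improved stove during a 12-month wedge, and the wedge is bracketed by 6-month
pre- and post-rollout observation phases so that every season is observed
both with and without the intervention. The default design is 12 groups of 4
sectors (48 sectors, roughly 35 eligible children under 36 months each),
observed over 24 monthly periods.

Because no field data ship with the package, a first-class synthetic-data
module generates every input the pipeline consumes — outcome panels, daily
symptom diaries, 10-second air-quality logger traces, and clustered
birthweights — each alongside its ground truth, so that every downstream
component can be validated by round trip.

## The analysis model

The primary analysis is a logistic mixed model for the binary child-period
ALRI indicator $Y_{ijt}$ (child $j$ in village/sector $i$ at period $t$):

$$\operatorname{logit} \Pr(Y_{ijt} = 1) =
  \alpha_0 + b_i + c_{ij} + s(t, v) + \theta X_{it},$$

with mean-zero normal random intercepts $b_i$ (village) and $c_{ij}$ (child),
a natural cubic spline $s(t, v)$ with $v$ degrees of freedom absorbing
seasonal and secular variation in ALRI risk, and the stepped-wedge exposure
indicator $X_{it}$. The log-odds stove effect $\theta$ is the target of
inference; it is tested with a Wald $z$ statistic.

`fit_alri_glmm()` maximizes the Laplace-approximate marginal likelihood.
Two engines are supported; both are Laplace and agree to well within
estimation error, so the choice is purely computational:

* **glmmTMB** (default): roughly 6 s per full-design panel (~40,000
  observations, ~1,700 random-effect levels) on one CPU;
* **glmer** (lme4): the classical reference implementation, several-fold
  slower, retained as an option and as a cross-check in the test suite.

An independent audit path, `fit_alri_glmm_agq()`, maximizes the *exact*
(nested Gauss–Hermite) marginal likelihood with `optim` on small panels. The
test suite verifies that the audit fitter and the Laplace engines agree on
$\hat\theta$ to better than 0.01 and that an independent quadrature
evaluation reproduces the engine log-likelihood.

### Choices the model leaves open

* **What is a "village"?** The trial's randomization groups contain 4
  sectors each, and sectors — not groups — are the units expected to carry
  outcome correlation (group sectors are deliberately spread geographically).
  `cluster_level` therefore defaults to `"sector"` (48 units) for both the
  random intercept and robust-variance aggregation, with `"group"` (12
  units) available.
* **Spline dimension.** A priori $v = 8$ (4 df per year of data); the
  sensitivity range 4–12 is automated in `sensitivity_over_v()`. $v = 0$
  (no time adjustment) is supported because the power study uses it to
  demonstrate trend-confounding bias. $v = 1$ is rejected.
* **Knots** sit at equally spaced quantiles of the observed periods, with
  boundary knots at the range and linear extrapolation beyond — the standard
  natural-spline construction (`splines::ns`).
* **Transition coding.** Stoves are installed throughout the crossover
  month, so that month is coded unexposed by default; `sw_design()` can
  instead code it exposed or drop it (`NA`).

### Robust variance

As a check on the assumed correlation structure, `robust_variance()`
computes a cluster-level sandwich covariance for the fixed effects. The
marginal likelihood of this model factorizes over clusters, so per-cluster
scores are well defined; they are evaluated by nested Gauss–Hermite
quadrature (variance components held at their estimates, the usual
fixed-effects sandwich) and differentiated by central finite differences.
The bread is the model-based covariance and a $G/(G-1)$ small-sample factor
is applied. The gradient norm at the MLE is reported as a diagnostic (near
zero for a converged fit). Following standard practice, when the robust SE
exceeds the model SE appreciably (`use_threshold`, default ratio 1.1) the
fit records that robust intervals should be used. No CRAN/Bioconductor
package in this toolchain provides cluster sandwiches for `glmer`/`glmmTMB`
fits, which is why this component is implemented here.

## The generative simulator

`simulate_panel()` draws outcomes from the same model family the analysis
assumes, under the trial's planning assumptions:

| Parameter | Default | Meaning |
|---|---|---|
| children per sector | Poisson(35) | eligible cohort size |
| baseline rate | 1.0 /child-year | marginal ALRI episode rate under the null |
| village variance | 0.025 | log-odds scale; rates vary ±30% across villages |
| child variance | 0.10 | log-odds scale; ±60% across children |
| seasonality | amplitude 1.05 | peak/trough rates 1.05× above/below average |
| secular trend | none / large | "large": +50% odds at $t=1$ decaying to 0 over 10 months |
| effect $\theta$ | −0.1 … −0.3 | 10–30% odds reductions |

Design choices worth recording:

* **Rate → probability mapping.** The binary period response is linked to
  the episode rate by $p_0 = \text{rate} / \text{periods per year}$
  (monthly default $p_0 = 1/12$). The intercept $\alpha_0$ is then
  *calibrated* — `calibrate_alpha0()` solves for the value at which the
  marginal response probability, integrating over both random intercepts by
  Gauss–Hermite quadrature and averaging over one seasonal cycle, equals
  $p_0$. Without this integration step the random effects would inflate the
  marginal rate a few percent above nominal (the expit is convex below
  one half).
* **Seasonality on the linear predictor.** The multiplicative seasonal
  factor enters as $\log(\text{amplitude}^{\sin(\cdot)})$ added to the
  log-odds. At $p \approx 0.08$, rate and odds multipliers are
  interchangeable to first order; this approximation is deliberate and
  its residual is absorbed by the calibration. The sinusoid is
  log-symmetric, so its geometric mean over a cycle is exactly 1 and the
  annual rate is season-invariant.
* **Season phase** defaults to a peak at month 3 (configurable); the
  seasonal peak month does not affect any calibration property, only which
  calendar periods are high-risk.
* **Period granularity** is monthly (24 periods). A weekly mode exists
  (boundaries mapped by 52/12); the monthly default matches the wedge's
  monthly steps and is what the power study uses.
* **Wedge order in power simulations** is held at the identity permutation:
  groups are exchangeable a priori, so power is invariant to the order, and
  a fixed order keeps replicate streams comparable across scenarios.

The diary generator plants episodes that *satisfy the case definition by
construction* (length ≥ 2 days, fever and fast/difficult breathing together
on at least one day, every episode day symptomatic, ≥ 7 symptom-free days
between episodes) and returns them as ground truth; noise days are isolated
single-symptom days placed at least 8 days from any episode so they can
neither extend nor merge with one. The logger generator composes a
(optionally drifting) baseline, raised-cosine cooking excursions,
multiplicative log-normal noise and 1–2-sample contamination spikes, and
returns the planted event windows.

**What the synthetic data do not emulate:** loss to follow-up, stove-use
non-compliance, reporting biases in maternal symptom recall, instrument
drift, or real cooking-diurnal patterns. Passing tests therefore demonstrate
the *internal* correctness and calibration of the machinery under the
planning model, not robustness to those field realities.

## Episode detection

The ALRI rule — "two or more consecutive days with fever and fast/difficult
breathing, both reported on at least one day, at least one symptom each day,
episodes separated by ≥ 7 symptom-free days" — contains two clauses that can
only hold simultaneously if symptomatic runs separated by 1–6 free days are
*merged* into one episode. `detect_episodes()` therefore: (1) finds maximal
runs of days with fever and/or fast/difficult breathing; (2) merges runs
separated by ≤ 6 symptom-free days; (3) keeps candidates spanning ≥ 2
calendar days that contain a both-symptoms day. Gap days inside a merged
episode are retained and counted (`n_gap_days`).

Interpretation switches: `both_same_day = FALSE` weakens the co-occurrence
reading to "each symptom on some day"; `bridge_missing = k` lets up to `k`
consecutive missing diary days act as symptom-free days instead of hard
breaks (the default is the conservative break). Severity follows the
examination thresholds with *strict* inequalities: respiratory rate > 50
(age ≥ 12 months) or > 60 (age < 12 months), chest retractions,
unconsciousness, or crackles in any quadrant; unexamined episodes are graded
not severe and flagged.

The detector is verified against an independent brute-force oracle — a
regular-expression formulation of the same printed rule — on **every**
two-symptom diary of length ≤ 10 (1.4 million diaries), and by exact
round-trip recovery of the generator's planted ground truth with and without
noise. Because the at-risk denominator is not uniquely defined,
`episode_summary()` reports episodes per child-year both including and
excluding in-episode days from person-time.

## Exposure metrics

The chain from a 10-second logger trace to a daily summary
(`exposure_summary()`):

1. optional pluggable calibration correction (e.g. nephelometer humidity
   correction), applied pointwise to raw samples *before* any averaging;
2. 10-minute averages by symmetric trimmed means — 3% per tail, floor of
   the sample count, so exactly one sample per tail for a nominal 60-sample
   interval; intervals with < 75% valid samples are flagged invalid;
3. running median of length 5 (shrinking windows of 3 then 1 at the ends,
   output length = input length) to remove short contamination excursions;
4. daily baseline = 10th percentile (linear-interpolation quantile, R type
   7 — pinned for bit-reproducibility) of the filtered values;
5. stove-influenced time (SIT): intervals whose *filtered* value strictly
   exceeds 1.2 × baseline;
6. SIP/SIC: the sum of (*unfiltered* 10-minute average − baseline) over SIT,
   in concentration × 10-min units, also reported as concentration-hours
   and rescaled to 24 h. The unfiltered series is the default integrand
   because filtering exists to *define* stove-influenced intervals, not to
   alter their measured mass; a switch integrates the filtered series.

A monitoring "day" is one deployment window (≥ 18 h to count as valid).
Two invariants pin the chain down: full scale equivariance (multiplying a
trace by $k > 0$ leaves SIT unchanged and scales SIP by exactly $k$) and
zero SIP for any constant trace. One subtlety found during exhaustive
testing: a *single* pass of the length-5 running median is not idempotent
with shrinking endpoint windows (e.g. the 0/1 sequence `0 1 1 0 0`);
repeated application does converge to a stable root within a few passes,
and that is the property the tests assert.

`stove_contrast()` estimates the before/after installation change in a
daily summary with household random intercepts, first-order harmonic season
terms and a centered secular slope, reporting both the annual contrast (all
measurements) and the immediate contrast (within ± 2 months of
installation; the secular slope is dropped there because a short window
cannot identify a slope on top of a step). Standard errors are model-based
and household-level sandwich (closed form for the linear mixed model).
Households observed on only one side are excluded and reported.

## Power and sample size

`run_power_cell()` / `run_power_grid()` reproduce the planning simulation:
generate a panel, fit the model, test $\theta = 0$ at $\alpha = 0.05$
(two-sided — the planning text does not state the size; 0.05 two-sided is
the convention), repeat, and report the rejection percentage with its
binomial Monte-Carlo SE. Non-converged replicates are excluded from the
denominator and counted. Replicate seed streams are keyed by the scenario
label, not by grid position, so cell results are independent of evaluation
order. Scaled-down grids (fewer sectors, smaller cohorts, fewer replicates)
are first-class: the scale is recorded in every result object.

At the full design, one cell of 100 replicates takes roughly 10 minutes on
one CPU with the default engine. Problem sizes used by the automated
checks, chosen to keep the suite brisk while leaving the assertions sharp:
the targeted power cell ($\theta = -0.3$, no trend, $v = 8$; planning value
99%) runs 100 replicates at the full design; the type-I-error check (400
replicates) and the 2-SE coverage check (100 replicates) run on a
desk-scale design of 12 groups × 1 sector with Poisson-6 cohorts, where a
fit takes ~0.4 s; the trend-confounding bias demonstration ($v = 0$ fitted
to large-trend data, expected bias magnitude ≳ 0.2) uses 6 full-design
replicates. Empirically, ignoring a large decaying trend with $v = 0$
pulls $\hat\theta$ from −0.1 to about −0.31 — exactly the failure mode the
spline adjustment exists to prevent — while $v \in \{2, 8\}$ fits remain
unbiased.

The closed-form calculators expose every assumption rather than a printed
bottom line: `mdd_continuous()` implements
$\delta = (z_{1-\alpha/2} + z_{\beta})\,\sigma\sqrt{2\,\mathrm{DE}/n}$ with
design effect $\mathrm{DE} = 1 + (m-1)\rho$, and `power_proportion()` the
two-sided normal-approximation power with the effective sample size
$n/\mathrm{DEFF}$. Published planning summaries that depend on unstated
cluster sizes or allocations cannot be reconstructed from their stated
inputs alone and are deliberately not asserted as numeric targets; the
calculators are instead validated against a hand-derived closed-form value
(50.5 g at $n = 1175$, $\sigma = 437$, no clustering) and an exact binomial
simulation (agreement within 2 percentage points).

## Numerical conventions

* Quadrature: Gauss–Hermite nodes by Golub–Welsch eigendecomposition;
  log-sum-exp throughout; 12–15 nodes per level are ample because the
  planning variances (0.025, 0.10) keep the integrands near-Gaussian.
* Finite differences: central, relative step $10^{-5}$.
* Reproducibility: every stochastic entry point takes a `seed`; derived
  streams use a deterministic 31-bit FNV-1a hash of a scenario key, so all
  seeds stay below $2^{31}$ and results are independent of evaluation
  order. All generators are bit-reproducible for a fixed seed.
* Interchange formats: tab-separated text with header rows, ISO-8601 dates,
  empty fields for missing values, 1-based closed period indices, units
  echoed in logger headers.

## Known limitations

* The Laplace approximation can be slightly conservative for binary data
  with small clusters; the AGQ audit fitter bounds that error on small
  panels but is not practical at the full design size.
* The sandwich holds variance components fixed at their estimates; their
  sampling variability is not propagated (standard for cluster-robust
  mixed-model practice).
* The weekly period mode approximates month boundaries by rounding 52/12
  multiples.
* `power_proportion()` is a normal approximation; at small effective sizes
  an exact test simulation is the better instrument (the package tests do
  exactly that comparison).
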