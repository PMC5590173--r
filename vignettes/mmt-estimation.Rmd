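---
title: "Monte Carlo estimation of the minimum mortality temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo estimation of the minimum mortality temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtsim)
```

## The model

Daily death counts $Y_t$ and daily mean temperatures $x_t$ are linked by
an overdispersed log-linear time-series model,

$$Y_t \sim \text{quasi-Poisson}(\mu_t), \qquad
\log \mu_t = \alpha + s(\mathbf{x}_t;\boldsymbol\eta)
  + \sum_j h_j(u_{jt};\boldsymbol\gamma_j),$$

where $s(\cdot)$ is a distributed lag nonlinear model (DLNM)
cross-basis: a quadratic B-spline $\phi_1,\dots,\phi_{v_x}$ on the
temperature axis crossed with a lag basis $\psi_1,\dots,\psi_{v_l}$, so
that $s(\mathbf{x}_t;\boldsymbol\eta)
= \sum_{j}\sum_{k} \mathbf{r}'_{tj}\mathbf{c}_k\,\eta_{jk}$. The
confounder block $h_j$ comprises six day-of-week indicator contrasts and
a natural cubic spline of the day index absorbing seasonality and trend.
Quasi-Poisson estimation means the point estimates coincide with the
Poisson maximum likelihood fit while the covariance is inflated by the
Pearson overdispersion estimate $\hat\phi = \chi^2_P/(n-p)$; we use the
Pearson estimator because it is the standard quasi-likelihood choice.

Cross-basis coefficients are reduced to the lag-cumulated curve by the
linear map $\boldsymbol\beta = \mathbf{M}\boldsymbol\eta$ with
$\mathbf{M} = \mathbf{1}'_{(L+1)}\mathbf{C} \otimes \mathbf{I}_{(v_x)}$,
and $V(\boldsymbol\beta) = \mathbf{M}V(\boldsymbol\eta)\mathbf{M}'$.
Coefficients are ordered with the temperature index varying fastest,
matching the Kronecker structure; the ordering is pinned by tests. When
the temperature metric is a moving average the cross-basis collapses to
a one-dimensional basis of the window mean and $\mathbf{M}$ is the
identity: the fitted coefficients already describe the cumulated curve.

**Spline parameterizations.** Quadratic B-splines are evaluated through
the B-spline design recursion; dropping the first column of the
intercept-augmented basis gives the no-intercept variant. Natural cubic
splines use the standard natural basis (linear beyond the boundary
knots). Any parameterization spanning the same function space yields
identical downstream results — fits, reductions and argmins depend only
on the span — so tests pin the span through independent oracles rather
than raw basis values. B-spline evaluation outside the boundary knots is
an error by default; boundary knots are placed at the observed data
range so this never triggers in normal use, and an explicit `"extend"`
policy (polynomial continuation) exists for the synthetic generator's
few partial-window head days. Lag knots default to values equally spaced
on the log-lag scale between $\log 1$ and $\log L$, kept as real numbers
rather than rounded to whole days.

## The MMT estimators

The MMT is the argmin of the lag-cumulated curve
$x \mapsto \mathbf{Q}_x\boldsymbol\beta$ over the observed temperature
range. All argmins are grid argmins on a 0.1 °C grid spanning the
observed range (the resolution is configurable; the observed range is
the natural domain because the curve is never extrapolated). Ties break
toward the lowest temperature, deterministically.

* **Argmin1** minimizes over the full range; **Argmin2** restricts the
  search to the 1st–99th observed percentiles, the usual guard against
  boundary solutions. Percentiles are computed by linear interpolation
  between order statistics, and the same definition is shared by prior
  supports and the cold/heat reference temperatures.
* **Empirical1** draws $\boldsymbol\beta_{(i)} \sim
  \text{MVN}(\hat{\boldsymbol\beta}, V(\hat{\boldsymbol\beta}))$ and
  records $\theta_{(i)} = \arg\min_x \mathbf{Q}_x\boldsymbol\beta_{(i)}$;
  the empirical mean (default; the median is available) and percentile
  interval summarize the distribution.
* **Empirical2** keeps only draws whose $\theta_{(i)}$ falls inside a
  uniform prior support $(\alpha_1,\alpha_2)$ — a truncation of the
  Empirical1 distribution, implemented by rejection on the same proposal
  stream. With a shared seed the restricted sample is *exactly* the
  unrestricted sample intersected with the support, which both tests and
  users can exploit for paired comparisons.

Monte Carlo draws use a symmetric eigendecomposition square root of
$V(\hat{\boldsymbol\beta})$ with eigenvalues clipped at zero
(covariances arriving through the reduction can be indefinite at
round-off level; anything below $-10^{-8}$ relative is an error, not
clipped). The default number of retained draws is 5,000. The rejection
sampler's budget is 100 × `n_sim` proposals; if the budget is exhausted
with an acceptance rate under 0.5 % the support is declared incompatible
with the data and the run fails loudly — a silent short sample would
masquerade as a valid posterior. When the final proposal block overshoots
`n_sim` acceptances, the stream is cut at the proposal that produced the
last retained draw, so the recorded acceptance rate is unbiased.

**Interval percentiles.** The default pair (2.5, 97.5) gives a central
95 % interval. For strongly right-skewed MMT distributions — typical of
sector-shaped associations whose minimum sits near the cold boundary —
the (0, 95) pair is more appropriate. There is no reliable automatic
rule for "skewed enough", so the pair is a caller choice; sample
skewness is reported alongside every result to inform it.

**Relative risks.** With the empirical methods, the RR at temperature
$x$ uses each draw's own MMT as reference,
$RR_{(i)} = \exp\{(\mathbf{Q}_x - \mathbf{Q}_{\theta_{(i)}})
\boldsymbol\beta_{(i)}\}$, preserving the pairing between $\theta_{(i)}$
and the $\boldsymbol\beta_{(i)}$ that generated it. With the argmin
methods the conventional fixed-reference estimate applies: a linear
contrast with the delta-method normal-approximation interval. The
empirical RR point estimate defaults to the mean, mirroring the MMT
choice; the skew-adjusted pair is available for RR intervals too.

## The synthetic scenario generator

The generator stands in for confidential city mortality data. It
emulates, per scenario:

* a multi-year daily temperature series: sinusoidal annual cycle (peak
  mid-July) plus AR(1) noise. Defaults — mean 15 °C, amplitude 14 °C,
  marginal noise SD 4.5 °C, lag-1 autocorrelation 0.6 — describe a
  continental mid-latitude climate and were chosen once so that the four
  canonical true MMTs sit at realistic percentiles of the exposure
  distribution: 23.889 °C ≈ 75th (U), 11.274 °C ≈ median (reverse-J),
  29.167 °C ≈ 90th (rotated-S), and −3.333 °C strictly *between* the 1st
  and 10th percentiles (sector) — the last point matters because the
  sector scenario's prior supports start at the 1st percentile, and a
  true MMT below the observed 1st percentile would contradict the
  scenario's own geometry;
* four association shapes with known true MMTs. Template curves (piecewise
  power functions; for the rotated-S a smooth interpolant through shape
  landmarks) are projected onto the quadratic B-spline basis by least
  squares under a zero-derivative constraint at the true MMT, with a
  small quadratic well escalated from negligible depth until the global
  fine-grid argmin lands on the target; the construction errors if the
  basis cannot achieve it. Curve amplitudes are anchored to cold/heat
  relative risks of realistic city-level magnitude (about 1.02–1.19 at
  the 1st/99th percentiles). The *realized* projected curve — not the
  template — is the truth the harness scores against, including its
  realized RRs;
* confounding: day-of-week log-rate effects of ±2 % and a smooth
  seasonal mortality cycle (amplitude 0.12, winter peak), which the
  fitted 8-df-per-year time spline is flexible enough to absorb;
* overdispersed counts. "Quasi-Poisson" names a variance assumption, not
  a generative family, so counts are drawn from a negative binomial with
  per-observation size $\mu_t/(\phi-1)$, whose variance is exactly
  $\phi\mu_t$; $\phi = 1$ degenerates to Poisson. The default
  $\phi = 1.3$ is a typical large-city value. The baseline of ~150
  expected deaths/day matches a large metropolitan area.

A simulation study holds one covariate realization (temperature and
calendar) fixed and redraws only the counts across replicates. This
mirrors how such studies are built from a real city's covariates, and it
makes the fitted basis (knots at the observed 10th/75th/90th exposure
percentiles) *identical* to the generating basis — the model is exactly
correctly specified, which is the regime in which coverage statements
about the samplers are meaningful. Replicate and Monte Carlo seeds are
spawned from the master seed and recorded in the output; empirical
methods within a replicate share one proposal stream.

What the generator does **not** emulate: real temperature series have
heat waves, cold spells and interannual variability beyond AR(1) noise;
real mortality has influenza epidemics, holidays, demographic drift, and
harvesting dynamics (short-term mortality displacement producing genuine
lag structure). Passing tests therefore demonstrate correctness of the
estimators under a correctly specified smooth model, not robustness to
the full messiness of surveillance data — interval coverage is known to
degrade when splines or knots are misspecified, and `run_study()`
accepts explicit basis overrides for such sensitivity experiments.

**Prior supports.** Per-scenario defaults at three informativity levels:
strong = 70th–95th percentiles (U, rotated-S), 40th–65th (reverse-J),
1st–10th (sector); moderate = 50th–99th (U, rotated-S), 30th–80th
(reverse-J), 1st–50th (sector); minimal = 1st–99th everywhere. (One
published table of these levels assigns "1st–50th" to the wrong scenario
by an apparent transposition; the assignment here follows the scenario
geometry — a cold-boundary minimum takes the low-percentile support.)

## Numerical choices and edge cases

* Quasi-Poisson fitting: IRLS convergence at relative deviance change
  $<10^{-8}$, at most 100 iterations, non-convergence flagged.
  Rank-deficient designs error naming the collinear column. Days lacking
  a complete lag history (the first $L$) are dropped, not padded.
* Time-spline df = `round(df_per_year × n_years)`; the rounding policy
  is a package decision since fractional-year series are not otherwise
  specified.
* Degenerate inputs: zero covariance collapses the MMT distribution to
  the argmin and all reference RRs to 1 (tested closed-form limits);
  empty samples and single-draw intervals are errors; a flat fitted
  curve returns the lowest grid temperature by the tie rule.
* Determinism: every user-facing sampler takes a seed and restores the
  caller's RNG state; studies record all spawned seeds, and rerunning
  from a manifest reproduces output files byte-identically.

## Problem sizes

The estimator-level checks use 200 replicates of 5-year series with
2,000 Monte Carlo draws per replicate — sizes at which the replicated
studies complete in tens of seconds while coverage estimates carry a
Monte Carlo standard error of about 1.5 percentage points. The package's
own evaluation (tests and `scripts/acceptance.R`) runs the U-shape
scenario for interval coverage of both empirical samplers and the sector
scenario for the skew-adjusted pair.

## Known limitations

* The prior over the MMT is restricted to a uniform support; graded
  prior beliefs across the range are not representable.
* The argmin point estimators carry finite-sample bias when the curve is
  flat near its minimum, and the bias grows as the information per
  replicate shrinks: at 5 years of data the constrained argmin's mean
  error in the U and rotated-S scenarios is measurably nonzero relative
  to its Monte Carlo standard error (the parameter-recovery test reports
  this honestly). This is a property of argmin functionals of noisy
  curves, not a defect of the implementation: the empirical samplers'
  interval coverage is the quantity designed to survive it.
* Coverage statements assume the fitted spline family and knots match
  the generating mechanism; misspecification can push intervals off the
  true MMT with confidently short lengths.
* The harness evaluates single-location series; pooling across locations
  (meta-regression, BLUPs) is out of scope.
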