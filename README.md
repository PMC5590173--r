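# mmtsim

Point and interval estimation of the **minimum mortality temperature
(MMT)** in nonlinear temperature–mortality associations, with the MMT
uncertainty propagated into cold- and heat-related relative risks, and a
simulation harness for evaluating the estimators.

## The problem

Daily mortality counts respond nonlinearly to ambient temperature: risk
rises at both cold and hot extremes, with a minimum at some intermediate
temperature — the MMT. The MMT summarizes population susceptibility and
serves as the reference temperature for cold/heat relative risks, yet it
is not a model parameter: it is the *argmin* of an estimated curve, and
its sampling uncertainty is easy to ignore and hard to characterize.

`mmtsim` is for environmental epidemiologists and biostatisticians who
fit quasi-Poisson time-series models with distributed lag nonlinear model
(DLNM) cross-bases and want defensible point and interval estimates for
the MMT and MMT-referenced relative risks.

## The model and the estimators

Daily deaths follow an overdispersed log-linear model

```
Y_t ~ quasi-Poisson(mu_t),   Var(Y_t) = phi * mu_t
log mu_t = alpha + s(x_t; eta) + day-of-week + smooth seasonal trend
```

where `s(x_t; eta) = sum_jk r'_tj c_k eta_jk` is a cross-basis coupling a
quadratic B-spline in temperature (knots at the 10th/75th/90th
percentiles) with a lag basis; a moving-average temperature metric is the
one-dimensional special case. Cross-basis coefficients reduce to the
lag-cumulated curve via `beta = M eta`, `M = (1'C) ⊗ I`, with covariance
`M V(eta) M'`.

Four MMT estimators operate on the reduced fit:

* **Argmin1 / Argmin2** — grid argmin of `Q_x beta-hat` over the observed
  range, unconstrained / constrained to the 1st–99th temperature
  percentiles. Point estimates only.
* **Empirical1** — parametric bootstrap: draws
  `beta_(i) ~ MVN(beta-hat, V(beta-hat))`, maps each to
  `theta_(i) = argmin_x Q_x beta_(i)`, and summarizes the empirical MMT
  distribution (mean point estimate, percentile interval).
* **Empirical2** — the same proposal stream filtered by rejection to a
  uniform prior support `(alpha_1, alpha_2)` for the MMT (e.g. the
  1st–99th percentiles for a minimally informative prior), shrinking the
  uncertainty when prior knowledge exists.

Relative risks comparing temperature `x` against the MMT propagate the
MMT uncertainty draw by draw, `RR_(i) = exp((Q_x - Q_theta_(i)) beta_(i))`,
or use the conventional fixed-reference delta-method interval for the
argmin estimators. Skewed MMT distributions (e.g. sector-shaped
associations) can be summarized with the 0th–95th percentile pair instead
of 2.5th–97.5th.

The `simulate` side generates synthetic multi-year daily series from four
association shapes with known true MMTs — U (23.889 °C), reverse-J
(11.274 °C), rotated-S (29.167 °C), sector (−3.333 °C) — with seasonal
AR(1) temperatures, day-of-week and seasonal mortality confounding, and
negative-binomial counts with variance exactly `phi * mu`, and scores the
estimators by bias, RMSE, coverage probability and mean interval length.

## Worked example

```r
library(mmtsim)

sc <- scenario_spec("u")            # U-shape truth, MMT 23.889 degC, phi 1.3, 5 years
d  <- generate_dataset(sc, seed = 42)
f  <- fit_mmt_model(d, ma_window = sc$ma_window)
f$fit
#> <qp_fit> 1824 obs, 5 cross-basis coefficients, dispersion 1.352

argmin_mmt(f$reduced, constraint = c(1, 99))
#> [1] 24.64413

mr <- sample_mmt(f$reduced, n_sim = 5000, prior = prior_support(1, 99), seed = 7)
mr
#> <mmt_result> empirical2: MMT 21.47 degC, 2.5%-97.5% interval [10.34, 25.94]
#>   5000 draws retained of 5086 proposed (skewness -1.31)

rr <- cold_heat_rr(f$reduced, mr)
rr$cold
#> <rr_result> RR at -5.16 degC vs empirical MMT: 1.0632 [1.0257, 1.1074]
rr$heat
#> <rr_result> RR at 34.60 degC vs empirical MMT: 1.0716 [1.0404, 1.1056]
```

The fitted dispersion (1.352) recovers the generating overdispersion
(1.3). The constrained argmin (24.6 °C) and the restricted empirical
point estimate (21.5 °C) bracket the true MMT of 23.9 °C; the empirical
interval [10.3, 25.9] quantifies how much of that range the data cannot
distinguish. The cold and heat relative risks compare the 1st and 99th
temperature percentiles against each draw's own MMT, so their intervals
carry the MMT uncertainty.

`tidy()`, `glance()` and `autoplot()` methods are available for fits,
MMT results and studies; `run_study()` + `study_metrics()` reproduce the
estimator-comparison tables, and `cmd_estimate()` / `cmd_simulate()` /
`cmd_curves()` (or the thin CLI in `inst/cli/mmt-cli.R`) drive the same
pipeline from configuration files.

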