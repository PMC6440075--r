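---
title: "Methods: distributed lag non-linear temperature–mortality models in tempmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed lag non-linear temperature-mortality models in tempmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempmort)
```

## The model

`tempmort` estimates the short-term association between daily ambient
temperature and daily death counts with a distributed lag non-linear
model (DLNM). Counts $Y_t$ are modelled as overdispersed Poisson with a
log link:

$$
\log E(Y_t) = \alpha + \delta_1 \mathrm{DOW}_t + \delta_2 \mathrm{HOY}_t
  + \mathrm{ns}(\mathrm{Date}_t) + cb(x_t, \dots, x_{t-L}), \qquad L = 30 .
$$

The calendar-time spline `ns()` absorbs long-term trend and seasonality;
weekday and holiday indicators absorb the within-week cycle. The
cross-basis $cb$ encodes the temperature effect along two dimensions at
once — the intensity of exposure and its delay:

$$
s(x, t) = \sum_{\ell=0}^{L} f\!\cdot\!\omega(x_{t-\ell}, \ell),
$$

with marginal bases $f(x)$ for the exposure-response shape and
$\omega(\ell)$ for the lag-response shape. Realized as a design block,
column $(j, k)$ at day $t$ is $\sum_\ell R_j(x_{t-\ell}) C_k(\ell)$ with
$R$ the exposure basis and $C$ the lag basis at integer lags. The model
is fitted by iteratively reweighted least squares (quasi-Poisson, log
link; relative deviance tolerance $10^{-8}$, at most 100 iterations), and
the coefficient covariance is scaled by the Pearson dispersion
$\hat\varphi = \chi^2_P / \mathrm{df}$.

Key assumptions: counts are conditionally independent given the smooth
terms (no residual autocorrelation beyond what the covariates induce);
variance is proportional to the mean; the temperature effect is additive
on the log scale and homogeneous over the study period.

## Cross-basis construction and identifiability

* **Marginal bases.** The exposure function is either linear (1 df) or a
  quadratic B-spline *without* intercept (2 + knots df); the lag function
  is either constant (1 df) or a quadratic B-spline *with* intercept
  (3 + knots df). Only one margin may carry an intercept — with both, the
  tensor product would contain the model intercept and be unidentifiable.
  B-spline values come from `splines::splineDesign` with the conventional
  augmented knot vector; the test suite checks them against a hand-coded
  Cox–de Boor recursion.
* **Centring and the reference temperature.** All exposure-basis columns
  are centred at a reference temperature, so the fitted RR is exactly 1
  there with zero variance. No external convention fixes the reference;
  the package defaults to the median of the training temperatures, and
  every reported RR is relative to it. It is overridable
  (`model_spec(ref_temp = )`), which matters when comparing a fitted
  curve with a known truth: both must share the reference.
* **Knot placement.** Exposure knots are placed at equal distances over
  the observed temperature range (1 knot at the midpoint, 2 at the
  thirds); lag knots at equal distances on the raw 0–30 scale (15; or 10
  and 20). Boundary knots sit at the data range. With one knot in each
  margin the cross-basis has $3 \times 4 = 12$ columns.
* **Leading rows.** The first $L$ days have incomplete lag histories and
  are dropped from the fit, never imputed. Season-restricted analyses
  (winter = Dec–Mar, summer = Jun–Sep) first compute lagged exposures
  from the full continuous series and then restrict outcome rows to the
  season, so January days draw lags from December.
* **Out-of-range temperatures.** Basis evaluation clamps temperatures to
  the boundary (constant extrapolation); prediction functions warn when a
  requested temperature lies outside the fitted range.

## Model selection

The candidate grid crosses 4 exposure functions, 4 lag functions and
trend flexibility 7–9 df/year: 48 models with cross-basis df from 1 to
20. Models are ranked by QAIC,

$$\mathrm{QAIC} = -2\,\ell_{\mathrm{Pois}} / \hat\varphi_{\mathrm{ref}} + 2k,$$

where $\ell_{\mathrm{Pois}}$ is the Poisson log-likelihood at the
quasi-Poisson fit (including the $\log y!$ term, constant across
candidates) and $k$ the number of coefficients. The dispersion reference
$\hat\varphi_{\mathrm{ref}}$ is taken from the most complex candidate and
shared by all, so candidates are compared on a common scale; per-model
dispersion would let an underfitting model flatter itself with an
inflated $\hat\varphi$. This convention is a package choice — the
literature uses both.

## Trend evaluation on new data

Predicting deaths for a validation period reuses the training
coefficients, so the training design must be rebuilt at validation dates.
A natural cubic spline with 7–9 df/year is linear beyond its boundary
knots, and its end slope reflects the local seasonal wiggle; extrapolated
over a multi-year horizon this produces exponentially exploding expected
counts. `tempmort` therefore never extrapolates the calendar spline:
out-of-range dates are folded back by whole years (same day-of-year) and
the basis row is averaged over all training years. The prediction keeps
the fitted mean seasonal profile while holding the secular level at the
training mean. The cost is that any true secular drift after the training
period is not projected — an explicit, conservative choice.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with a known ground truth for recovery experiments:

* **Temperature**: an annual sinusoid (peak mid-July) plus stationary
  AR(1) noise; `tmin`/`tmax` subtract/add a positive diurnal half-range.
  Defaults (annual mean 15&nbsp;°C, semi-amplitude 6&nbsp;°C, AR
  coefficient 0.7, innovation sd 2&nbsp;°C) describe a mild maritime
  climate of the Iberian Atlantic coast.
* **Truth surface**: separable, $s(x, \ell) = f(x)\, w(\ell)$, with
  exponentially decaying lag weights normalized to sum to 1 over lags
  0–30 (e-folding 5 days by default) and a piecewise-quadratic exposure
  function: zero with zero slope at the reference, rising to the cold
  effect (default log-RR 0.5) at the analytic 1st-percentile temperature
  and the heat effect (0.15) at the 99th. Because the lag weights sum to
  1, the overall cumulative log-RR at sustained temperature $x$ is
  exactly $f(x)$. Anchor temperatures are derived from the scenario's
  marginal temperature distribution by quadrature, not simulation, so the
  truth is a deterministic function of the scenario.
* **Counts**: negative-binomial with per-day size $\mu/(\varphi - 1)$, so
  the variance/mean ratio equals the scenario overdispersion *exactly*
  (with $\varphi = 1$, Poisson). This makes the quasi-Poisson variance
  assumption correct by construction, which is deliberate: the coverage
  experiment then measures interval calibration, not variance-model
  misspecification. Baseline 15 deaths/day, overdispersion 1.5, weekday
  effects up to 0.06 on the log scale, a smooth seasonal log-rate cycle
  of semi-amplitude 0.1 (peak mid-January), and fixed-date public
  holidays. Weekday/holiday magnitudes are chosen for testability — no
  published reference magnitudes exist for them.
* **Climate-model twin**: `distort_temperature()` applies location,
  scale, upper-tail and noise distortions, mimicking the systematic bias
  of dynamically downscaled simulations.

What the generator does **not** emulate: heat waves as episodes (AR(1)
noise has no clustering beyond autocorrelation), harvesting/mortality
displacement, influenza epidemics, demographic drift, multi-region
correlation, or measurement error in exposure. Passing recovery tests on
this generator therefore shows the estimator works when its assumptions
hold; it does not validate those assumptions for real data.

Population is constant by default; as a constant covariate it is
unidentifiable next to the intercept and is dropped from designs with a
warning.

## Bias correction

`fit_quantile_map()` matches empirical quantiles of the simulated series
to observed quantiles at probabilities $(1..n)/(n{+}1)$, $n = 99$ by
default (percentile mapping — the common convention when the source
method does not state its grid). Corrections interpolate monotonically
between matched quantiles; ties in the simulated quantiles (flat CDF
regions) are collapsed to the mean observed quantile. Beyond the
outermost quantiles the default rule applies a constant offset — linear
extrapolation of an empirical QQ relation amplifies exactly the extremes
one most wants corrected; a linear-extrapolation rule is available.
`bias_correct_series()` fits per-season maps (winter/summer/other) by
default because the downstream analysis is seasonal and model bias
typically differs between cold and warm months; whether the original
calibration was seasonal is not documented, so this is a package default,
not a reproduction.

## Validation

* **Effect validation** compares lag-specific log-RR effects from
  independently fitted training and test periods over a fixed grid: lags
  0–30 crossed with the training 1st/50th/99th percentile temperatures.
  Metrics are the relative RMSE and relative MAD, both normalized by the
  *mean* test effect; a zero mean is reported as undefined rather than
  infinite.
* **Prediction validation** resamples validation days i.i.d. with
  replacement (50 resamples by default), computing the RMSE of predicted
  versus resampled observed deaths with training coefficients reused —
  no refitting. Day-level resampling ignores serial dependence; for
  strongly autocorrelated residuals a block bootstrap would be more
  faithful, and this is a known limitation of v1.

## The parametric bootstrap study

`run_simulation()` measures how cross-basis choice affects the *overall
cumulative effect*: the cumulative log-RR at a single summary
temperature — by default the 1st percentile (99th for summer analyses),
matching how cold/heat effects are conventionally reported. The
generative truth is either a fitted model (its fitted means,
coefficients and dispersion) or a synthetic scenario. Each of $m$
replicates regenerates counts on a contiguous block of $n_s$ days
(default $500 \times 2000$) with negative-binomial noise, refits each
candidate scenario (covariate designs are prebuilt once; only the
outcome changes), and records the scalar estimate and its delta-method
variance. Summary indices: percent bias, empirical 95% coverage, percent
RMSE, all normalized by the true effect. Candidate refits share the
truth's reference temperature so every estimate targets the same
contrast. Replicate fit failures are excluded and reported; a scenario
with fewer than 90% surviving replicates is flagged unreliable.

## Numerical choices

* IRLS: `glm.fit`, tolerance $10^{-8}$, max 100 iterations;
  non-convergence and rank deficiency are errors (the latter names the
  collinear columns), not warnings.
* Wald intervals use 1.96 on the log scale throughout.
* Dispersion: Pearson $\chi^2$ over residual df.
* Quantile type 7 (R default) for all empirical quantiles.
* Seeds: every stochastic function takes an explicit seed; scenario
  generators derive temperature and mortality streams from `seed` and
  `seed + 1`.

## Problem sizes in the test suite

The suite exercises the full-scale constants where the statistics demand
them — coverage from $m = 500$ replicates of $n_s = 2000$ days, recovery
on 5&nbsp;000-day series, dispersion calibration at $n = 20\,000$ — and
smaller sizes (800–2&nbsp;000 days, $m$ = 5–40) for structural and
determinism checks, chosen so each property is identifiable at its
tolerance. The model-selection consistency experiment uses 20 replicates
of 5-year series against the full 48-model grid. The under-flexibility
comparison uses a deliberately strong, curved truth (cold log-RR 0.9,
baseline 25 deaths/day): with mild effects the comparison at small $m$ is
dominated by estimator variance and the lack-of-fit ordering is not
identifiable.

## Known limitations

* No penalized DLNMs, natural-spline or threshold exposure functions;
  the model space is exactly the 48-candidate grid.
* Wald intervals only (no bootstrap CIs for the curves themselves).
* Day-level bootstrap ignores serial dependence.
* Secular trend is not projected beyond the training period when
  predicting.
* Single region at a time; no multi-site pooling or meta-analysis.
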