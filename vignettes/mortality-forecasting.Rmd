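---
title: "Forecasting cause-specific mortality with Lee-Carter and Bayesian age-period-cohort models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting cause-specific mortality with Lee-Carter and Bayesian age-period-cohort models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcforecast)
library(dplyr)
```

## The problem

Planning health services requires projections of future death counts, and
those projections are dominated by two opposing forces. Population ageing
pushes counts up: mortality from degenerative disease rises roughly
exponentially with age, so a population whose density shifts towards the
oldest bands generates more deaths even at fixed rates. Secular declines in
age-specific death rates, such as the sustained fall of coronary heart
disease mortality in high-income countries since the late 1970s, push counts
down. A projection that freezes today's rates (the common planning
counterfactual, here called the *constant-rate scenario*) answers a
different question from a projection that lets the observed decline continue
(the *trend scenario*). `apcforecast` implements both ends of that
comparison as a pipeline: data containers for mortality surfaces, two
forecasting models, hold-out validation to pick between them, and scenario
projection of death counts against a population projection.

All user-facing functions take tabular inputs (one row per sex x age-band x
year cell) and return tibbles, so the stages compose with the pipe.

## Data model

A **mortality surface** holds death counts `D[i, j]` and mid-year
populations `N[i, j]` for `I` age bands and `J` consecutive years, one sex
at a time. Age bands are closed-open `[lower, lower + C)` of a common width
`C` years, with an optional open-ended top band ("85+"), which we treat as a
regular group because nothing in the data bounds its exposure. From the
surface we derive the central death rate `m = D / N` and the death
probability under the constant-hazard-within-interval convention

\[ q = 1 - \exp(-m). \]

The two scales coexist deliberately: the Lee-Carter model works on log
central rates, while the Bayesian age-period-cohort (BAPC) likelihood is a
binomial on the probability scale. The `q = 1 - exp(-m)` bridge (with
mid-year population as the binomial exposure, the only exposure available)
makes the two models comparable cell by cell; it is convex, so `q <= m`
always, and the difference is `O(m^2)` — negligible below age 85 and about
2% at the highest observed rates.

## The Lee-Carter model

`fit_lee_carter()` decomposes the log central rate as

\[ \log m_{x,t} = a_x + b_x k_t + \varepsilon_{x,t}, \]

with `a_x` the average age schedule, `k_t` a single mortality index carrying
the time dynamics, and `b_x` the age-specific sensitivity to the index. The
fit is the textbook two-stage procedure: `a` is the row mean of `log m`;
`(b, k)` is the leading singular pair of the row-centred matrix, rescaled to
the conventional gauge `sum(b) = 1`, `sum(k) = 0`; then each `k_t` is
re-estimated by a one-dimensional root search so that predicted total deaths
given the exposures match the observed annual totals (the standard
second-stage adjustment; the variant used is recorded in the fit object, and
`adjust_k = FALSE` disables it). Zero-death cells would break the logarithm,
so they receive a documented offset (`zero_offset = 0.5` added to the death
count) before logging; national CHD surfaces have no zero cells, but
synthetic or sparse data may.

Forecasting extrapolates `k` as a random walk with drift — ARIMA(0,1,0)
with constant, the canonical Lee-Carter choice — with drift
`(k_J - k_1)/(J - 1)` and innovation standard deviation estimated from the
drift-corrected first differences. The point forecast follows the drift
path; intervals come from simulated paths (2.5/97.5 percentiles), so the
95% band half-width on the log scale is `1.96 * sd * sqrt(h) * |b_x|` at
horizon `h`, a closed form the test suite checks by simulation. Two choices
were genuinely open and are exposed as flags: the jump-off anchors at the
last *observed* log rates by default (avoiding a jump-off bias when the
last fitted value misses the last observation) with `jump_off = "fitted"`
available; and the model is fitted directly on the grouped `I x J` grid —
an age-smoothing pre-step can be injected through the `smooth` hook, but no
default smoother is imposed because its tuning parameters would be
arbitrary and smoothing does not change the model comparison logic.

## The Bayesian age-period-cohort model

`fit_bapc()` models the logit of the death probability as

\[ \mathrm{logit}(q_{ij}) = \mu + \theta_i + \varphi_j + \psi_k
   \;(+\, z_{ij}), \qquad k = C(I - i) + j, \]

with `D_ij ~ Binomial(N_ij, q_ij)`. The cohort index `k` maps each cell to
a birth cohort when age bands are `C` times wider than periods; over a full
grid there are `K = C(I-1) + J` distinct cohorts (83 for the 6 x 33
configuration). Each effect block gets a Gaussian random-walk smoothing
prior of first or second order with a Gamma-distributed precision
(default `Gamma(1, 5e-5)`, weakly informative and configurable). The optional `z_ij` is i.i.d. Gaussian
cell-level heterogeneity absorbing overdispersion beyond the APC structure;
extreme cohorts supported by few cells get the same prior as the rest — no
ad-hoc shrinkage.

Second-order walks are the default for all three blocks because their
predictive mean continues the local linear trend, which is exactly the
"let each component continue along its last observed linear trend"
behaviour wanted for trend scenarios; `"rw1"` (level continuation) is
available per block.

### Sampler

Estimation is Metropolis-within-Gibbs, implemented in C++: single-site
Gaussian random-walk proposals for the intercept and every effect and
heterogeneity parameter, with per-parameter step sizes adapted during
burn-in towards the single-site optimum of ~44% acceptance
(Roberts-Rosenthal diminishing adaptation, frozen after burn-in), and
conjugate Gamma updates for the block precisions. Defaults are 4 chains of
50,000 iterations, 20,000 burn-in, thinning 10; all seeds are explicit and
chains are bitwise reproducible. Initialisation is empirical (grand-mean
logit plus row/column margins), which matters: started from zero effects,
the heterogeneity block can absorb the period trend and trap the chain in
a poor mode.

### Identifiability

The likelihood identifies only the linear predictor: block levels can trade
against the intercept, and because `cohort = period - age` a linear trend
can move freely among the three blocks. The sampler handles the two
flat directions differently:

* block levels are recentred into the intercept every iteration
  (measure-preserving, since RW priors depend only on differences and the
  intercept prior is flat);
* when all three blocks are RW2, the cohort block's linear component is
  projected out each iteration and compensated exactly in the age and
  period blocks (`gamma*k = gamma*C(I-i) + gamma*j`), again
  measure-preserving because RW2 priors are invariant to linear shifts.
  With any RW1 block that direction is pinned by the prior and no
  projection is applied.

Forecasts are functions of the identified predictor only, so they cannot
depend on the reporting gauge; the test suite checks the predicted
probabilities agree to machine precision under two different gauges applied
to the same chains. For interpretation, `decompose_effects()` applies a
declared gauge to every draw — sum-to-zero per block plus removal of the
cohort block's linear component (attributed to the period trend and age
schedule) by default, with a period-detrending alternative — and reports
each block's share of cell-level linear-predictor variance. This gauge is a
declared choice of this package rather than a convention inherited from
any particular APC software.

### Prediction, DIC

`predict()` extends, per retained draw, the period and cohort blocks by
their RW predictive distributions at that draw's precisions and (optionally,
default on) draws future heterogeneity from its prior — omitting it would
understate predictive spread. Intervals are the 2.5/97.5 percentiles of the
resulting probability draws, and widen monotonically with horizon for fixed
precisions (`h/tau` predictive variance for an RW1 block, checked against
the closed form). `dic()` reports `DIC = Dbar + pD`, `pD = Dbar - D(etabar)`
with the deviance focused on the cell-level linear predictor (the
conventional choice for hierarchical rate models) and the
binomial log-likelihood including its combinatorial constant, so a
degenerate posterior gives `DIC = -2 log L` exactly.

The binomial likelihood itself is a documented choice: the model is
written on the mortality *probability* scale, which the binomial matches;
a Poisson variant of the generator exists for Lee-Carter checks.

## Scenarios and validation

`scenario_constant()` multiplies the last observed death probabilities by
the projected population (`deaths = q * N`, with `m * N` behind a flag —
they differ at `O(m^2)`); its uncertainty bounds, when requested, are
binomial sampling variation around the frozen rates — a construction of
this package, documented as such, since constant-rate counterfactuals have
no canonical interval.
`scenario_forecast()` applies a model forecast per draw to the same
projection; feeding it frozen rates reproduces the constant scenario cell
by cell, which the tests require exactly. `percent_change()` compares
yearly totals to a reference year (default: the last observed), propagating
intervals per draw; `combine_scenarios()` sums single-sex results.

`compare_models()` backtests candidates by fitting on years up to a split,
forecasting the hold-out window, and tabulating the mean absolute percent
error per age stratum,

\[ \mathrm{MAPE} = \frac{100}{T} \sum_t \frac{|y_t - \hat y_t|}{y_t}, \]

computed on rates (counts behind a flag), with zero observed cells excluded
and counted. The overall summary is the unweighted mean across strata, and
the per-year denominator convention is the standard one; both are stated
rather than assumed. The winner is the lowest MAPE, ties broken by supply
order.

## The synthetic-data generator

Nothing in the pipeline requires proprietary data: `sim_config()` +
`simulate_surface()` generate surfaces with the structure the analysis
assumes, and the generating effects are returned so recovery is testable.
The generator builds `logit(q) = mu + theta_i + phi_j + psi_k (+ z_ij)`
with

* an age-exponential baseline (defaults from ~3 per 10,000 at 35-44 to
  ~4.5 per 100 at 85+, the scale of CHD mortality in England & Wales around
  1979);
* a linear-plus-quadratic period trend (default drift −0.04/yr — a
  sustained decline halving rates roughly every 17 years — with an optional
  decelerating curvature);
* small smooth cohort effects: a second-order random walk on the same
  `k = C(I-i)+j` grid the model uses (so recovery aligns one-to-one),
  detrended so they do not alias the period drift, scaled to a default
  amplitude of 0.05;
* optional i.i.d. heterogeneity, and binomial (default) or Poisson death
  draws.

`simulate_projection()` ages the population geometrically per band,
`N[i, J] (1+g_i)^t`; the default growth rates are backed out of cumulative
19-year shifts of +35%, +50% and +89% at 65-74, 75-84 and 85+ (+4-10%
below 65), the published ageing pattern for England & Wales to 2030. The
default geometry is `I = 6`, `C = 10`, `J = 33`, horizon 19 — the 1979-2011
observation window projected to 2030.

What the generator does *not* emulate, and hence what passing tests do not
establish about real data: age-varying period trends (the logit trend is
common to all ages, whereas real CHD declines decelerated more in middle
age), migration and cohort-size dynamics in the population projection
(growth is geometric per band, not cohort-component), ICD coding changes,
and any black-swan discontinuity. Parameter-recovery results on these
surfaces demonstrate correctness of the estimators under the model's own
assumptions, not robustness to their violation.

## Numerical choices and problem sizes

Tolerances and sizes used by the test suite are part of the package's
design: exact identities (scenario consistency, gauge invariance of
forecasts, MAPE arithmetic) are tested to 1e-10/1e-12; noiseless Lee-Carter
recovery to 1e-8; stochastic checks run at desk scale — 6 x 33 grids,
exposures 1e4-1e6, 20-seed replications for directional claims (DIC with
versus without heterogeneity; drift recovery within three Monte-Carlo
standard errors). The MCMC correctness anchor is a 2-age x 2-period toy
with RW1 priors and fixed precisions, where the five-dimensional posterior
on the identified slice is integrated on a dense grid and the sampler's
posterior mean intercept must agree within 0.02. Root-finding in the
Lee-Carter adjustment uses `uniroot` to 1e-10 on a bracket spanning the
SVD index; a fully time-constant surface short-circuits to uniform
loadings and a flat index rather than failing in the SVD.

## An end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(
  simulate = list(I = 6, J = 33, horizon = 19, overdispersion_sd = 0.05),
  model = "bapc",
  model_args = list(heterogeneity = TRUE),
  split_year = 2001,
  project = TRUE,
  seed = 1
)
manifest <- run_pipeline(cfg, "run1")
```

writes the surface and projection CSVs, a tidy fit summary, the three-way
validation table (constant vs Lee-Carter vs BAPC), both scenario tables
with percent changes, and a JSON manifest with seeds, the config echo and
per-file checksums; rerunning with the same config and seed reproduces the
checksums. `run_pipeline()` is also the package's single orchestrated entry
point (simulate -> fit -> validate -> project) for use from scripts.

## Known limitations

* The APC linear trend is not estimable from data; the reported
  decomposition depends on the declared gauge (forecasts do not).
* RW2 cohort extrapolation at long horizons inherits the posterior
  uncertainty of the terminal cohorts, which few cells support; credible
  intervals for the oldest bands grow accordingly wide.
* Lee-Carter's single index assumes a time-constant age pattern of change;
  when that fails (as it does for CHD at the oldest ages) its hold-out
  error grows, which is precisely what the validation stage is for.
* Scenario uncertainty for the constant-rate counterfactual is binomial
  only; it ignores the (counterfactual) uncertainty of the frozen rates
  themselves.
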