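# apcforecast

Forecasting cause-specific death rates and death counts on age-group ×
calendar-year grids, for epidemiologists and health-service planners who
need to contrast two futures: the common planning counterfactual that
current mortality persists unchanged, versus the continuation of an
observed secular decline. The package grew out of the coronary heart
disease setting — rates that fall steadily while the population ages — but
works for any cause tabulated by sex, age band and year.

## What it implements

**Lee-Carter.** log m<sub>x,t</sub> = a<sub>x</sub> + b<sub>x</sub>k<sub>t</sub> + ε<sub>x,t</sub>,
with a<sub>x</sub> the mean log-rate schedule and the mortality index
k<sub>t</sub> the single time dynamic: first singular pair of the centred
log-rate matrix (gauge Σb = 1, Σk = 0), second-stage re-estimation of
k<sub>t</sub> to match annual death totals, and forecasting of k as a random
walk with drift.

**Bayesian age-period-cohort (BAPC).**
logit(q<sub>ij</sub>) = μ + θ<sub>i</sub> + φ<sub>j</sub> + ψ<sub>k</sub> (+ z<sub>ij</sub>),
k = C(I−i) + j, with D<sub>ij</sub> ~ Binomial(N<sub>ij</sub>, q<sub>ij</sub>),
first- or second-order random-walk smoothing priors per block, Gamma
precision hyperpriors, optional i.i.d. heterogeneity z, and an adaptive
Metropolis-within-Gibbs sampler written in C++. RW2 priors (the default)
make each component continue its local linear trend when predicted, which
is what a trend scenario needs. Model support is compared by DIC; effect
interpretation uses an explicit identifiability gauge that never touches
the forecasts.

**Validation and scenarios.** Hold-out backtesting by mean absolute
percent error (MAPE) per age stratum picks the forecasting model; scenario
A multiplies last-observed death probabilities by a population projection,
scenario B applies a model forecast per posterior draw, and
`percent_change()` summarises both against a reference year.

**Synthetic data.** `sim_config()`/`simulate_surface()` generate surfaces
with the assumed structure (age-exponential baseline, decelerating period
decline, small smooth cohort effects, overdispersion) and return the
generating truth; `simulate_projection()` ages the population geometrically
per band. Every stage of the pipeline is testable without any external
data.

## A worked example

Thirty-three years of synthetic male CHD-like data (six ten-year bands,
sustained decline, mild overdispersion), backtested on the last ten years,
then projected nineteen years against an ageing population:

```r
library(apcforecast)

cfg  <- sim_config(seed = 1, overdispersion_sd = 0.05)
sim  <- simulate_surface(cfg)
proj <- simulate_projection(cfg)

compare_models(sim$surface,
               models = list(constant   = "constant",
                             lee_carter = lc_control(),
                             bapc       = bapc_spec(chains = 2, iter = 20000,
                                                    burn = 8000,
                                                    heterogeneity = TRUE)),
               split_year = 2001, seed = 1)
#> overall MAPE (unweighted mean over strata): constant 21.75%,
#> lee_carter 7.45%, bapc 5.57%
#> best overall: bapc
```

Frozen rates misforecast a declining series badly (21.8% error, growing
with horizon); the BAPC model, which also captures the small cohort
structure, beats Lee-Carter (5.6% vs 7.4%). Refit on the full window and
project:

```r
fit <- fit_bapc(sim$surface, bapc_spec(chains = 2, iter = 20000, burn = 8000,
                                       heterogeneity = TRUE, seed = 1))
decompose_effects(fit)$variance_shares
#>   age 0.953, period 0.046, cohort 0.0006, heterogeneity 0.0008

fc  <- predict(fit, horizon = 19, seed = 1)
tail(percent_change(scenario_constant(sim$surface, proj,
                                      n_sims = 1000, seed = 1)), 1)
#>    year pct_change lower upper
#>    2030       47.6  46.1  49.3
tail(percent_change(scenario_forecast(fc, proj, observed = sim$surface)), 1)
#>    year pct_change lower upper
#>    2030      -25.1 -65.3  35.3
```

Read: if 2011 rates persisted, ageing alone would raise annual deaths 47.6%
by 2030 (23,547 → 34,752); if the fitted decline continues, deaths fall
25.1% (to 17,626) despite the same ageing — though with the wide credible
interval long-horizon trend extrapolation deserves. The age effect
dominates the linear predictor's variance, then period, then cohort,
matching how such surfaces are generated.

`autoplot()` methods exist for fits, forecasts, scenario results and
validation reports; `tidy()`/`glance()` give broom-style summaries;
`run_pipeline()` drives the whole chain from a config list or YAML file and
writes CSV artifacts plus a checksummed manifest.

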