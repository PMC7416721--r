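# regtrend

Detecting and estimating population declines from short, noisy time
series of abundance estimates — the situation conservation monitoring of
cetaceans and other hard-to-survey taxa is usually stuck with: a handful
of survey estimates (3–13 points is typical), coefficients of variation
of 0.1–0.5, and a legal mandate to say whether the population is
declining.

`regtrend` provides:

* a **simulator** for the standard data-generating mechanism: abundance
  estimates `ŷ_t` with lognormal observation error at `T` evenly spaced
  occasions, analysed as ratios `p̂_t = ŷ_t / ŷ_1` to the first
  (baseline) estimate;
* three **trend estimators** for the no-intercept log-linear model, and
* a **Monte Carlo engine** that measures their long-run frequency
  properties — power, type-I error, type-S error (wrong sign among
  significant results), type-M error (exaggeration ratio), bias and
  confidence-interval coverage — over factorial scenario grids;
* **case-study tools** for real series: annual growth rates and
  expanding-window stability analyses, plus a small CLI.

## The model

The true trajectory is geometric: the proportion of the population
remaining at occasion `t` is

```
p_t = r^((t-1)/(T-1)),        so   p_1 = 1  and  p_T = r,
```

where `r` is the fraction of the initial population remaining at the end
of the study period (`r = 0.5` is a 50% overall decline). On the log
scale this is a line through the origin,

```
log p_t = x_t * beta,   x_t = (t-1)/(T-1) in [0, 1],   beta = log r,
```

so the analysis is a linear regression of log abundance ratios on scaled
time with **no intercept** (the baseline ratio is identically 1). The
slope is estimated three ways:

1. **unregularized** — ordinary maximum likelihood;
2. **informative prior** — maximum a posteriori under a normal prior on
   `beta` centred at 0 with scale `log(2)/2`, spanning a halving to a
   doubling of the population;
3. **weakly-informative prior** — MAP under a Cauchy prior centred at 0
   whose scale `-log(2)/tan(pi*(xi - 1/2))` encodes a small skeptical
   probability `xi` that the population at least halves or doubles; at
   `xi = 0.025` the no-trend null has prior odds 39:1. Fitted by a
   scale-mixture-of-normals EM.

The point of the regularized fits: the shared baseline noise (`ŷ_1`
appears in the denominator of every ratio) makes the naive regression
reject a true no-trend null far more often than its nominal level, while
the heavy-tailed Cauchy prior shrinks such spurious trends to zero yet
gives way when the data carry a strong, consistent signal.

## Worked example

```r
library(regtrend)
set.seed(42)

# a synthetic 10-year survey of a population declining 5% per year,
# observed with CV = 0.2
series <- generate_case_fixture(10, year_start = 2007,
                                annual_rate = 0.95, cv = 0.2,
                                name = "synthetic-dolphin")
fit <- fit_trend(to_ratio_series(series), weakly_informative_prior(),
                 alpha = 0.20)
fit
#> Trend fit, cauchy prior (scale 0.05455)
#>   beta (log r): -0.01843  se 0.03796  df 9  p = 0.6388
#>   r (remaining fraction): 0.98173  80% CI [0.93153, 1.03465]
annual_growth_rate(fit, span_years = 9)
#> Annual growth rate 0.9980 (80% CI 0.9922-1.0038) over 9 years (p = 0.639)
```

This draw is noisy enough that the skeptical prior (rightly, at this
sample size) shrinks the apparent trend almost to zero: the estimated
remaining fraction 0.98 is not significantly below 1 at the 20% level.
The Monte Carlo engine quantifies this trade-off:

```r
null_scen <- scenario(T_occasions = 10, r = 1, cv_lower = 0.1, cv_upper = 0.3)
run_scenario(null_scen, "unregularized", alpha = 0.05, n_reps = 2000, seed = 1)$rejection_rate
#> [1] 0.419     # naive regression: 42% false alarms at the 5% level
run_scenario(null_scen, "cauchy", alpha = 0.05, n_reps = 2000, seed = 1)$rejection_rate
#> [1] 0.055     # weakly-informative prior: 5.5%, at the nominal level
```

The CLI exposes the same functionality from a shell
(`inst/cli/regtrend`): `make-fixture`, `fit`, `stability` and
`simulate-grid` subcommands; grid sweeps are configured by a YAML file
and written as tidy CSV (column schema in
`inst/extdata/metrics-schema.csv`).

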