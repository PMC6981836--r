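# ccwin — short time-window case-crossover analysis of daily time series

`ccwin` estimates the short-term association between an environmental
exposure (typically ambient air pollution) and a daily health outcome,
using time-stratified case-crossover designs on *daily counts* rather than
individual case–control records. It is aimed at environmental
epidemiologists who analyse daily mortality/morbidity series and want an
estimator that is robust to seasonal confounding that spline-adjusted
time-series regression fails to remove.

## The model

Days are grouped into small calendar strata, and the slope β of outcome on
exposure is estimated with the per-stratum nuisance level eliminated. For
daily counts y with exposure x and linear predictor
η_i = β·x_i + covariates, conditioning the Poisson likelihood on each
stratum total Y_s = Σ_{i∈s} y_i gives the conditional log-likelihood

    ℓ(β) = Σ_s [ Σ_{i∈s} y_i η_i − Y_s log Σ_{i∈s} exp(η_i) ],

a per-stratum multinomial in which the stratum intercepts cancel. This is
the count-level equivalent of conditional logistic regression on matched
sets, and its maximiser coincides with the exposure coefficient of an
ordinary Poisson regression carrying one indicator per stratum. For a
continuous response the analogue is least squares with per-stratum
intercepts profiled out by within-stratum centering (Frisch–Waugh).

Available stratifications:

| scheme  | stratum                                      | window |
|---------|----------------------------------------------|--------|
| `CC2D`  | \<year : two consecutive days\>              | 2 days — the shortest possible |
| `CC3D`  | \<year : three consecutive days\>            | 3 days |
| `CC2W`  | \<year : two-week block : day of week\>      | 2 weeks, ≤ 2 days per stratum |
| `CC2CW` | chained (overlapping) two-week blocks × dow  | interior weeks used twice |
| `CCM`   | \<year : month : day of week\>               | the classical 1-month window |

The classical comparator — outcome regressed on exposure, day-of-week and a
natural cubic spline of time with a fixed df/year — is provided as
`fit_time_series_glm()` (`GLM6`, `GLM12`). A simulator
(`sim_config()` / `generate_study_set()`) produces 10-year series with a
known slope β = 1 and a periodic confounder sharing the exposure's
mid-range frequencies (periods 183/75 days, plus 105/68 in the richer
scenarios), the regime where the 6 df/year spline is biased while the
two-day design is nearly unbiased.

## Worked example

```r
library(ccwin)
cfg    <- sim_config(sim_id = 2, seed = 7)   # scenario 2: four shared periodicities
sample <- generate_sample(cfg, 0)            # 3650 days, true slope = 1

fit_method(sample$series, "CC2D")
#> CC2D fit (gaussian family): beta = 0.984652, se = 0.00671686, 95% CI [0.971487, 0.997817]
#>   records = 3640, strata = 1820, loglik = 3108.1742, converged = TRUE (1 iter)

fit_method(sample$series, "GLM6")
#> GLM6 fit (gaussian family): beta = 0.362082, se = 0.0204862, 95% CI [0.321928, 0.402235]
#>   records = 3650, strata = -, loglik = -6862.8185, converged = TRUE (2 iter)
```

The two-day conditional fit recovers the unit slope to within 1.6% while
the 6 df/year spline GLM on the same series is attenuated to 0.36: the
seasonal confounder at periods the spline cannot resolve leaks into its
slope, but differences between adjacent days carry almost none of it.
`run_simulation_study()` repeats this over many samples and
`summarize_to_table()` lays the order statistics out in the conventional
stacked beta/SE table.

For real count data:

```r
cfg    <- series_config(outcome_col = "cvd", exposure_col = "pm10",
                        temperature_col = "temp", family = "poisson")
series <- read_daily_csv("chicago.csv", cfg)
run_epi_analysis(series, stratum_scheme("CC2D", "calendar"),
                 model_spec("poisson", temperature_spline_df = 3), lag = 0)
```

A command-line wrapper with `simulate` / `fit` / `study` / `validate`
subcommands ships at `system.file("cli", "ccwin.R", package = "ccwin")`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates study sets for scenarios 1 and 2 under the given seed, fits
the conditional designs and the 6 df/year comparator to every sample,
prints the summary table, and writes the result manifest to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
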