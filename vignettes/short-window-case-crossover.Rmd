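---
title: "Short time-window case-crossover designs: models, numerics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short time-window case-crossover designs: models, numerics and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccwin)
```

## The problem

Daily health counts (mortality, hospital admissions) and daily pollutant
concentrations share strong temporal structure: season, weather, influenza,
day-of-week. The classical time-series remedy regresses the count on the
exposure plus a smooth function of calendar time, typically a natural cubic
spline with a fixed number of degrees of freedom per year. When exposure
and outcome share periodic structure at frequencies the spline cannot
resolve — periods of a few months at 6 df/year — the leftover confounding
leaks into the exposure slope, and no realistic df choice fixes it.

The case-crossover family sidesteps smoothing altogether: days are grouped
into small calendar strata, comparisons are made only *within* a stratum,
and everything that is constant within a stratum — including any smooth
confounder, to first order — is eliminated rather than estimated. `ccwin`
implements this on daily counts, down to the shortest possible window of
two consecutive days.

## Models

### Conditional Poisson regression

With counts $y_i$, linear predictor $\eta_i = \beta x_i + z_i'\gamma$, and
strata $s$, conditioning each stratum's Poisson likelihood on its total
$Y_s = \sum_{i\in s} y_i$ yields

$$\ell(\beta,\gamma) = \sum_s \Big[ \sum_{i \in s} y_i \eta_i
  - Y_s \log \sum_{i \in s} e^{\eta_i} \Big],$$

a multinomial per stratum in which the stratum intercepts cancel. Two
identities anchor the implementation and its tests:

* the maximiser equals the exposure coefficient of an *unconditional*
  Poisson regression with one explicit indicator per stratum (the profile
  log-likelihood differs from $\ell$ by a constant), which provides an
  independent oracle via `glm()`;
* when every stratum is a pair with outcomes in $\{0,1\}$, $\ell$ is
  exactly the matched-pair conditional-logistic likelihood, connecting the
  count formulation to the classical event-level case-crossover model. The
  event-level conditional logistic model itself is deliberately not
  implemented: the count form is the same likelihood with fewer records.

### Conditional Gaussian fit

For a continuous response the analogue is least squares with one intercept
per stratum. By Frisch–Waugh this is computed by centering the response and
every regressor within stratum and running OLS on the centered data.
Residual degrees of freedom are $n - S - p$ ($S$ strata, $p$ slope
parameters), exactly as if the indicators had been estimated, and standard
errors use the residual mean square on that df. Whether the original
`gnm`-based analyses used a dispersion-adjusted or unit-variance standard
error is not documented; the residual-df OLS convention is adopted here as
the defensible default and the oracle tests pin the fit to `lm()` with
explicit indicators to 1e-8.

### Stratification schemes

All schemes anchor at each year's day 1. "Year" is either the calendar year
(real data; day-of-year runs 1..366 and Feb 29 participates normally in its
pair or triple, so no day is silently dropped) or consecutive 365-day
blocks (`year_rule = "fixed365"`, for simulated series of exact 365-day
years; the span must divide by 365 unless `allow_partial_year = TRUE`).
Week numbering for the two-week schemes runs in 7-day blocks from day 1
regardless of weekday — the construction is specified "within a year" but
not anchored to a weekday, and anchoring at day 1 makes strata reproducible
— while the day-of-week level is the true calendar weekday. Trailing days
that do not fill a block form short strata rather than being merged
backward; that convention is what makes a 365-day year yield exactly 183
two-day strata (182 pairs plus one singleton). `CCM` always takes year and
month from the actual calendar dates, even under `fixed365`, because a
month is inherently a calendar notion. Stratum ids are deterministic
strings `<year>:<block>[:<dow>]`, so runs are bit-reproducible.

The chained scheme `CC2CW` duplicates interior weeks into their two
neighbouring strata. This nearly doubles the number of records and
mechanically narrows the reported standard errors; since the duplicated
records are not independent, those naive SEs are optimistic. The package
reproduces this behaviour faithfully (it is a property of the design, and
the study harness asserts the SE ordering against `CC2W`) and flags it here
as a caveat rather than attempting a correction.

### Informative strata

The conditional likelihood is untouched by strata that cannot inform the
slope: singletons, strata with constant exposure and — under Poisson —
strata whose counts sum to zero. The fitters filter these internally
(`informative_strata()` is idempotent, so pre-filtering is harmless), which
also makes the invariance "dropping uninformative strata changes nothing"
hold by construction. One nuance: under the Gaussian family a
constant-exposure stratum does carry information about the residual
variance, so retaining it would shift the SE even though the slope is
unchanged; filtering uniformly keeps the two families' record-keeping
consistent and the conditional likelihood well defined.

### Covariates under stratum elimination

Day-of-week enters as a treatment-coded factor (Monday reference — the
coding affects only the nuisance coefficients, never $\beta$) for the
consecutive-day schemes, where weekday varies within strata. Under `CC2W`,
`CC2CW` and `CCM` weekday is a level of the stratum itself; the fitters
detect any covariate whose within-stratum variance is below 1e-10 (relative
to the column scale) in every stratum and drop it with a notice, since the
conditional likelihood cannot identify it. Ambient temperature, when
requested, enters through a natural cubic spline (3 df is the conventional
choice for daily mortality work) with knots placed by the quantile rule on
the analysis dataset's own temperature distribution — knot placement is not
otherwise documented for this model family.

## Numerics

The conditional Poisson likelihood is concave; the optimizer is
Newton–Raphson with analytic gradient and Hessian on internally
standardised columns, step-halving on any likelihood decrease, convergence
when the maximum absolute score falls below 1e-8 or the step below 1e-10,
and a 100-iteration cap. Negative-semidefiniteness of the Hessian is
asserted at every iterate. A monotone likelihood (e.g. a single pair with
counts (0,1), where the conditional likelihood $e^\beta/(1+e^\beta)$ is
maximised only in the limit) is detected as a standardised coefficient
escaping beyond 10 and reported as `converged = FALSE` with a direction
note, never as a spuriously "converged" huge estimate. Confidence
intervals are 95% Wald throughout ($\hat\beta \pm 1.96\,\mathrm{se}$); no
level is prescribed by the source analyses, and no overdispersion/
quasi-likelihood scale is modelled — a documented limitation, matching the
model family implemented.

The natural spline basis is `splines::ns`: boundary knots at the data
range, interior knots at equally spaced quantiles, linear beyond the
boundaries. The time-series comparator uses
`round(df_per_year × years-span)` total df, with the span measured in days
and divided by 365.25.

## The simulator's stated world

Each sample is 10 years × 365 days (3650 days) with true slope
$\beta = 1$:

$$x_t = \sum_k a_k \sin(2\pi t/P_k + \phi_k) + e_t, \qquad
  y_t = \beta x_t + \sum_k b_k \sin(2\pi t/P_k + \psi_k) + \varepsilon_t.$$

Scenario 1 uses shared periods {183, 75} days; scenario 2 adds {105, 68};
scenario 3 keeps scenario 2's signals but replaces white background noise
with AR(1); scenario 4 scales both background noises by 2. The published
description of the scenarios defers all generative constants to an
external appendix and repository, and names two periods while speaking of
"three additional signals" — an internal inconsistency; the generator adds
exactly the two named periods. Every constant is therefore an explicit,
documented argument, with defaults fixed once from first principles:

| parameter | default | why |
|---|---|---|
| `exposure_amplitudes` $a_k$ | 1 | unit periodic signal per component |
| `confounder_amplitudes` $b_k$ | 1.5 | confounder comparable to, slightly stronger than, the signal |
| `phases` $\phi_k$ | 0 | deterministic signal; `"random"` draws them per sample |
| `phase_offset` $\psi_k-\phi_k$ | $2\pi/3$ | $\cos = -1/2$: partial opposition, so confounding biases downward without the knife-edge exact cancellation of anti-phase |
| `noise_sd_exposure` | 0.5 | day-to-day exposure variation comparable to within-pair signal differences |
| `noise_sd_outcome` | 0.1 | outcome noise small relative to exposure variation, as in the published slope sds of order 1e-3 |
| `ar1_coef` | 0.7 | visibly autocorrelated background, marginal sd preserved |
| `noise_scale` (scenario 4) | 2 | "scaled by a factor of the two background noises" with the factor unstated |

These defaults have closed-form consequences that the acceptance checks
measure rather than assume. After the 60-df time spline removes
fluctuations slower than roughly 120 days, the comparator's slope is
approximately $1 + \sum_{k'} a_k b_k \cos(\psi_k-\phi_k)/2 \big/
(\sum_{k'} a_k^2/2 + \sigma_e^2)$ over the unremoved periods $k'$
(75 in scenario 1; 75, 105, 68 in scenario 2), i.e. about 0.50 and 0.36 —
a large bias. Within two-day pairs the same covariance is damped by
$(2\sin(\pi/P_k))^2$, leaving the conditional estimate near 0.985. The
simulator is *not* a re-implementation of the original generator and
claims no distributional identity to it (whether scenario 1's generator is
scenario 2's with zeroed extra amplitudes is likewise unknown there; here
it is, by construction); consequently the study harness reproduces the
published *qualitative* contrast — near-unbiased short-window estimates
where the spline GLM fails, chained SEs smaller than unchained — but not
the published table values, which require the authors' published sample
files (`load_published_samples()` accepts such a directory and feeds it
through the identical harness).

What a green simulation test establishes, therefore: the estimators, the
stratification bookkeeping and the failure mode are correct on series with
this structure. What it does not establish: behaviour under real-data
features the generator omits — trends, holidays, irregular missingness,
overdispersed counts, exposure measurement error.

Per-sample randomness uses a counter-derived seed from
`(master seed, sample index)` (all arithmetic kept below $2^{31}$), so
study sets are bit-reproducible and independent of how many samples are
drawn; generation restores the caller's RNG state.

## Study harness conventions

Quartiles use linear interpolation between order statistics (R's default
type 7) — the convention of the published tables is unknown, so the choice
is recorded in each run's manifest. Non-converged fits are excluded from
summaries and counted, never imputed. The 12 df/year comparator (`GLM12`)
is available but not part of default runs. The real-data configuration for
a Chicago-style analysis (counts, PM10/ozone, temperature at 3 df, lag 0,
95% CI) ships as the worked `series_config()` pattern in the README; no
such data are bundled, and exact reproduction of that analysis is out of
scope. Exposure lag defaults to 0 days; the CI level to 95% — both
surfaced as arguments.

## Known limitations

* Naive SEs under record duplication (`CC2CW`), as discussed above.
* No overdispersion adjustment in the Poisson fits.
* No event-level referent sampling; the classical ±7k-day referent scheme
  is described here only as background.
* Calendar gaps are tolerated (strata simply hold fewer days) but lag
  arithmetic is positional, so heavily gapped series should be lagged with
  care.
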