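# mwmar — moving-window multivariate autoregressive models

`mwmar` detects **time-varying species interactions, environmental
effects, and community stability** in multispecies abundance time series.
It is aimed at ecologists with long monitoring records (plankton counts,
fish surveys, rodent trapping...) who suspect that the *strengths* of food-web
interactions shifted over the record — after a nutrient regime change, an
invasion, or a management intervention — and who want those shifts
quantified with uncertainty, not assumed away by a single stationary fit.

## The model

The core is the MAR(1) (first-order vector autoregressive) community
model on the log-abundance scale,

```
X_t = A + B X_{t-1} + C U_t + E_t ,
```

with `X_t` the p-vector of log abundances, `A` intrinsic growth constants,
`B` the p×p interaction matrix (diagonal = density dependence), `C` the
p×q matrix of effects of standardized environmental covariates `U_t`, and
`E_t` independent mean-zero process errors with diagonal covariance.
Coefficients are estimated by **conditional least squares**, equation by
equation, with a priori excluded links held at exactly zero via masks.
Community stability is `lambda`, the spectral radius of `B` — small means
fast return to the stationary distribution, above 1 means unstable.

Instead of one whole-series fit, the model is refit on every overlapping
window of `w` time steps (`n − w` windows for an `n`-step series), turning
each coefficient and `lambda` into a *time series of estimates* indexed by
window end time, with percentile bootstrap confidence intervals (2000
replicate data sets per window by default). Preprocessing utilities turn
raw sampling records into monthly panels: monthly means, log transforms
with explicit zero policies, and temperature climatology/anomaly
decomposition with full-series standardization.

## Worked example

A built-in generator produces a synthetic 33-year monthly panel of four
plankton guilds (diatoms/greens `DG`, other crustaceans `NDC`, `Daphnia`,
and the cyanobacterium `Oscillatoria`) with a mid-series regime shift from
a high-nutrient, *Oscillatoria*-dominated state to a clear-water,
*Daphnia*-dominated state:

```r
library(mwmar)
fx <- lake_washington_fixture(seed = 1)
fx$y
#> <abundance_panel> 396 time steps x 4 taxa (1962-01 .. 1994-12)
#> taxa: DG, NDC, Daphnia, Oscillatoria

tr <- moving_window_fit(fx$y, fx$u, fx$mask, w = 84)
tr
#> <mar_trajectory> window size 84, 312 windows (312 fitted, 0 failed)
```

Every coefficient is now a trajectory. The effect of *Oscillatoria* on
*Daphnia* in the window ending October 1979, with bootstrap intervals:

```r
win <- enumerate_windows(396, 84)
ys <- panel_slice(fx$y, win$data_start[130], win$response_end[130])
us <- panel_slice(fx$u, win$data_start[130], win$response_end[130])
fit <- fit_mar(ys, us, fx$mask)
ci <- bootstrap_intervals(fit, ys, us, n_boot = 2000, seed = 42)
#> window ending 1979-10: Oscillatoria -> Daphnia = -0.52, 95% CI [-0.67, -0.43]
```

a significantly negative per-capita effect while the two taxa overlap;
late in the series the same trajectory returns to non-significance. The
stability trajectory peaks during the transition:

```r
lam <- vapply(tr$results, function(r) r$lambda, numeric(1))
#> least stable window ends 1976-08 with lambda = 0.974
```

and residual diagnostics flag exactly the zero-inflated taxa:

```r
residual_normality_scan(tr, 0.05, "per_taxon")
#> <normality_report> 312 windows, m = 312 (per_taxon), corrected alpha = 0.00016
#> rejections per taxon:
#>           DG          NDC      Daphnia Oscillatoria
#>            0            0           54          114
```

Real data enter through `read_panel_csv()` (wide monthly CSV) or
`aggregate_monthly()` + `log_abundance()` + `build_covariate_panel()` for
raw records; `default_lake_washington_mask()` ships the four-guild a
priori food web (15 of 16 interactions; phosphorus restricted to the
phytoplankton guilds). A command-line front end with subcommands `fit`,
`mwfit`, `simulate` and `diagnose` is installed at
`inst/cli/mwmar`.

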