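---
title: "Moving-window MAR models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving-window MAR models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwmar)
```

## The model

`mwmar` works with first-order multivariate autoregressive (MAR(1), also
called VAR(1)) models of community dynamics on the log-abundance scale:

$$X_t = A + B\,X_{t-1} + C\,U_t + E_t,$$

where for $p$ interacting taxa and $q$ environmental covariates, $X_t$ is
the $p$-vector of natural-log abundances at time $t$, $A$ is a vector of
intrinsic per-capita growth constants, $B$ is the $p \times p$ interaction
matrix (off-diagonal entries are inter-specific per-capita effects,
diagonal entries express density dependence — values nearer 0 mean stronger
density dependence), $C$ is the $p \times q$ matrix of covariate effects,
and $E_t$ is a vector of process errors, independent mean-zero normals with
per-taxon variances $\sigma^2_i$ (a diagonal error covariance). Covariates
enter contemporaneously ($C U_t$, not $C U_{t-1}$): abiotic forcing is
taken to act within the same monthly step it is measured.

Community stability is summarized by $\lambda$, the spectral radius of $B$
(`stability_lambda()`). $\lambda$ governs the rate of return to the
stationary distribution after a perturbation: small values mean fast
return, and $\lambda > 1$ indicates an unstable system. We use the largest
eigenvalue *modulus* because the spectrum of an interaction matrix is often
complex and only the modulus carries the return-rate interpretation.

## Estimation: conditional least squares

`fit_mar()` estimates each equation independently by conditional least
squares (CLS): taxon $i$'s log abundance at $t$ is regressed on an
intercept, the mask-included lagged abundances, and the mask-included
covariates, minimizing the summed squared one-step prediction errors. This
is the classical estimator for MAR community models and, with independent
equations, it makes missing data simple to treat honestly: a regression row
with a missing response or predictor is dropped *for that equation only*
(casewise deletion). No interpolation or imputation is ever performed.
$\sigma^2_i$ is the residual sum of squares over the number of rows used
(maximum-likelihood divisor; an unbiased $n-k$ divisor is available via
`sigma2_divisor = "df"`).

A priori model structure is expressed with `mask_spec()`: excluded
coefficients are exactly zero in every output and their columns never enter
the design matrix, so exclusions change the degrees of freedom of nothing
but their own equation. The diagonal of the $B$ mask must be estimated —
a community model without density dependence terms is not meaningful here.
No stationarity constraint is imposed: windows with $\hat\lambda > 1$ are
reported as such, because transiently unstable estimates are themselves a
finding, not an error.

Degenerate designs (a taxon constant over a window, too few usable rows)
raise an error naming the offending equation; `moving_window_fit()` records
such windows as explicit failures rather than silently dropping or
"rescuing" them with ridge penalties.

## Moving windows

`enumerate_windows(n, w)` produces response ranges
$[2, w+1], [3, w+2], \dots, [n-w+1, n]$; each window additionally consumes
the observation before its first response to supply the lag. The window
count is $n - w$: 396 monthly steps with $w = 84$ give 312 windows. The
default window size of 84 steps (seven years of monthly data) is the
smallest multiple of 12 above the ~75-step threshold below which estimation
accuracy degrades sharply in simulation (see the window-size experiment
below); multiples of the seasonal period keep every window's seasonal
coverage balanced.

Covariates are standardized once over the *full* series, never per window,
so that coefficient trajectories reflect changing biological responses
rather than changing covariate scaling. All results are indexed by the
window END time, the convention natural for monitoring: the value plotted
at a date uses only data up to that date.

## Bootstrap confidence intervals

`bootstrap_intervals()` is a fixed-design parametric bootstrap: each
replicate series is rebuilt by iterating the fitted model forward from the
window's first observed state with the observed covariates held fixed and
random process errors, then refit by CLS. Two error-draw modes are
provided:

* `"residual"` (default): resample whole rows of the fitted residual
  matrix with replacement. Rows are kept intact to preserve cross-taxon
  error dependence, and the method is robust to the non-normal residuals
  that zero-inflated taxa produce.
* `"gaussian"`: draw from mean-zero normals with the fitted variances,
  matching the model's own error assumption.

Intervals are percentile bounds — order statistics of each coefficient's
replicate sample at $(1-\gamma)/2$ and $1-(1-\gamma)/2$ — with defaults
$n_{boot} = 2000$ and $\gamma = 0.95$. We use plain percentile intervals
rather than bias-corrected variants deliberately: they are the simplest
faithful reading of "refit under resampled errors", and they keep the
procedure transparent. The cost is a known, mild undercoverage: CLS
autoregressive estimates carry a small-sample downward bias (order
$(1+3b)/T$ for self-effects), the replicate world inherits it, and
percentile intervals do not re-center. In our coverage experiments
(`bootstrap_coverage_experiment()`, 2-taxon model, window-length panels of
85 steps, 600 pooled outer replicates) empirical coverage of a nominal 95%
interval for a self-effect sits near 0.89–0.92. Users needing exact
coverage for short windows should lengthen the window or treat borderline
significance calls conservatively.

A coefficient is called significant when its interval excludes zero
(`is_significant()`).

## Preprocessing

Raw monitoring records (arbitrary sampling dates) pass through:

1. `aggregate_monthly()` — arithmetic means within calendar months;
   unsampled months stay missing and the index stays contiguous.
2. `log_abundance()` — natural log with an explicit zero policy for months
   when a taxon was present in the system but absent from samples. The
   default adds, per taxon and only when that taxon has zeros, an offset
   $\delta$ equal to half its smallest positive observed value; the
   alternatives treat zeros as missing (they are then casewise-deleted in
   fitting) or use a fixed user $\delta$. The policy and per-taxon deltas
   are recorded on the returned panel, because the choice measurably
   shifts coefficient estimates for rare taxa and must be reportable.
3. `seasonal_decompose()` / `build_covariate_panel()` — temperature is
   split into a climatology (the 12 calendar-month long-term means,
   expanded along the series as a periodic "season" signal) and anomalies
   (deviations carrying warm/cold events and trends); both, and the raw
   phosphorus series, are standardized to mean 0, sample SD 1 over the
   full series. Phosphorus is not log-transformed by default; nothing in
   the method requires it and the raw scale keeps the trend
   interpretable. Abundances are log-transformed but not z-scored by
   default (`standardize()` is available when scale-free comparison of
   $B$ entries across taxa matters more than interpretability).

## Diagnostics

`residual_normality_scan()` applies the Shapiro–Wilk test (Royston's
approximation via `stats::shapiro.test`) to every window-by-taxon residual
vector at a Bonferroni-corrected level. The multiplicity universe is
ambiguous in practice — one can count all windows × taxa as one family
("pooled", the default, $m = 1248$ for the four-guild, 312-window layout)
or correct within each taxon's windows ("per_taxon", $m = 312$) — so both
conventions are computed and the report states $m$. Rejections concentrate
in taxa with zero-inflated stretches: the offset policy maps a run of
zero months to a point mass in log abundance, leaving one-sided residual
tails, which is exactly what the test should flag.

`residual_data_correlation_scan()` is the standard CLS misfit check:
within each window, each equation's residuals are correlated against that
equation's own predictor series (optionally all columns); a well-specified
model leaves roughly the nominal $\alpha$ fraction significant. Constant
residuals or predictors have no defined correlation and are flagged
degenerate rather than counted significant. `qq_export()` pairs residual
order statistics with normal quantiles at plotting positions
$(i - 0.5)/n$ (the symmetric standard choice).

## The synthetic four-guild community

`lake_washington_fixture()` generates a 396-step monthly panel of four
plankton guilds — DG (diatoms and green algae), NDC (non-daphnid
cladocerans and non-cladoceran crustaceans), *Daphnia*, and the
filamentous cyanobacterium *Oscillatoria* — emulating a lake recovering
from sewage-driven nutrient loading. Three piecewise-constant phases are
used (breakpoints at steps 169 and 241):

* **Eutrophic** — *Oscillatoria* dominant with strong negative effects on
  *Daphnia* (−0.5) and DG (−0.3); *Daphnia* rare, frequently below the
  detection floor. $\lambda = 0.946$.
* **Transition** — weakened density dependence; the least stable phase
  ($\lambda = 0.992$), so the estimated stability trajectory peaks
  mid-series.
* **Clear-water** — *Daphnia* dominant and structuring the community
  (effects on DG −0.4 and NDC −0.3); *Oscillatoria* rare and often
  censored. $\lambda = 0.666$.

Intrinsic growth vectors are solved from target stationary log-abundance
means via $A = (I - B)\mu$, covariate effects are constant across phases,
and the covariates themselves are a seasonal temperature cycle with
anomalies plus a mild warming trend, and a phosphorus series that declines
early (nutrient diversion) then flattens. Zero-inflation is implemented as
censoring below per-taxon detection floors on the count scale, after which
the ordinary `log_abundance()` zero policy applies — mimicking months when
a rare taxon escapes detection.

The fixture emulates the *structure* of such a monitoring record — regime
shifts, seasonality, a nutrient trend, detection-limited rare taxa — but
not several features of real data: observation error on abundances (the
model attributes all noise to process error), non-Gaussian process noise,
within-month sampling heterogeneity, or taxonomic aggregation error.
Passing tests on the fixture therefore demonstrate that the estimator and
intervals behave correctly when the model class is right, not that the
model class is right for any particular lake.

Two caveats from the fixture's own behaviour are worth knowing. First,
censoring attenuates: in phases where a taxon sits mostly at its
detection floor, estimated effects on that taxon shrink toward zero
relative to the latent truth (the early *Oscillatoria*→*Daphnia* effect
surfaces at reduced magnitude until *Daphnia* is regularly observed).
Second, windows fully containing a censored constant stretch can fail as
degenerate; they are reported, not hidden.

## Simulation experiments

`window_size_experiment()` quantifies the precision/accuracy trade-off
behind the choice $w = 84$: panels are simulated from the eutrophic-phase
parameters with the synthetic covariates, and each candidate window is
fitted at a fixed end-of-series anchor. Mean RMSE of off-diagonal $B$
entries falls monotonically with window size (roughly 0.22, 0.12, 0.087,
0.060 at 24, 48, 84, 168 steps over 50 replicates), with the collapse
steepest below ~75 steps; the observed RMSE ratio between 48 and 84 steps
is about 1.4–1.5, beyond the $\sqrt{84/48} \approx 1.32$ expected from row
count alone because short windows also lose effective rank against the
seasonal covariate structure.

`transition_bias_experiment()` measures the estimator while a simulated
system crosses a regime boundary: windows wholly inside a regime are
unbiased to Monte-Carlo precision, and straddling windows interpolate
monotonically between the two regime values — the bias any user must keep
in mind when reading trajectories near known change points, and the reason
estimates during transitions should be interpreted as window averages
rather than instantaneous states.

`regime_recovery_experiment()` is the end-to-end check: on two-regime
simulations (an own-dynamics drop from 0.8 to 0.3 at mid-series, T = 300,
$w = 84$), bootstrap intervals on wholly-pre and wholly-post windows cover
their regime's true coefficient in roughly 85–90% of windows, and the
stability trajectory runs from the first regime's spectral radius to the
second's.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the smallest sizes that keep Monte-Carlo error well below the
effect sizes being checked: 100 random small instances for the
CLS-vs-numeric-minimizer equivalence (tolerance $10^{-6}$); 50 replicates
for the window-size experiment; 200 outer × 500 bootstrap replicates for
coverage; 20 seeds × every third eligible window × 200 replicates for the
regime-shift recovery; $T = 50{,}000$ for the scalar closed-form moment
checks (2% tolerance); and a full 312-window moving-window run with
diagnostics on the synthetic community. The bootstrap default of
$n_{boot} = 2000$ applies to real analyses; experiments use smaller
replicate counts because only interval endpoints near the 2.5%/97.5%
quantiles are needed, not publication-grade intervals.

## Known limitations

* One-step CLS with diagonal error covariance: no observation-error
  (state-space) variant, no higher-order lags, no cross-equation error
  terms.
* Percentile intervals undercover mildly for strongly autocorrelated
  taxa in short windows (see above).
* The zero-offset policy is a pragmatic device, not a detection model;
  for severely zero-inflated taxa a censored-likelihood approach would be
  preferable and is out of scope here.
* Moving windows smear change points over a window length by
  construction; the method detects and localizes change only to window
  resolution and is not a change-point estimator.
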