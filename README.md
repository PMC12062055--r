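# dmdcast

Spatiotemporal analysis and one-step forecasting of county-level disease
incidence panels with **exact dynamic mode decomposition (DMD)**, benchmarked
against five standard forecasters.

## The problem

Public-health surveillance produces county-by-year panels of age-adjusted
incidence rates (e.g. lung cancer cases per 100,000 across ~1,000 US counties
over two decades). Practitioners want to (a) forecast next year's rate in
every county, and (b) understand the *spatiotemporal structure* of the panel
— which regions load on the dominant long-term trend, whether that trend is
decaying, and how much of the signal a low-rank description captures. Machine
learning regressors handle (a) but are opaque and expensive; DMD handles both
at the cost of a single SVD and delivers interpretable spatial modes, each
evolving geometrically with a complex eigenvalue.

## The method

Arrange the rates as snapshots `X = [x_1 … x_m]` (one column per year, one
row per county) and form the shifted pair `X1 = [x_1 … x_{m−1}]`,
`X2 = [x_2 … x_m]`. Assuming a linear propagator `X2 ≈ A X1`, exact DMD
identifies the leading spectrum of `A = X2 X1†` without ever forming the
n×n matrix:

1. reduced SVD `X1 ≈ U Σ V*` at rank `r`;
2. reduced operator `Ã = U* X2 V Σ⁻¹` (r×r);
3. eigendecomposition `Ã W = W Λ` — the `λ_k` are eigenvalues of `A`;
4. exact modes `Φ = X2 V Σ⁻¹ W`;
5. amplitudes `b` from the least-squares fit `Φ b ≈ x_1`;
6. prediction `x_k = Φ Λ^{k−1} b`.

`|λ| < 1` means the mode decays, `arg λ` its oscillation frequency per year;
the per-county magnitudes of the dominant zero-frequency mode give a
join-ready table for choropleth maps of the long-run spatial pattern. The
comparators are Holt exponential smoothing with trend (α = 0.2 by default),
lagged linear regression, random forest, gradient-boosted trees, and
RBF-kernel support vector regression with exhaustive grid search scored by
training RMSE. All forecasts are scored by RMSE and Spearman rank
correlation against the held-out year.

Because registry data of this kind sit behind data-use agreements, the
package ships a synthetic generator that simulates panels from a known
low-rank linear dynamical system (default: one slowly decaying real mode,
`λ = 0.97`, with a spatially clustered high-loading block, plus an
oscillatory conjugate pair `0.9 e^{±0.6i}`, plus observation noise), keeping
the ground truth alongside the panel so every stage has a parameter-recovery
test.

## Worked example

```r
library(dmdcast)

panel <- generate_panel(generator_config(n_counties = 200, n_years = 22, seed = 7))
fit <- dmd_fit(build_snapshots(panel, 2000:2020), rank = 3)
fit
#> <dmd> rank 3 fit of 200 counties x 21 snapshots (years 2000-2020)
#>   numerical rank of X1: 20
#>   leading eigenvalues: 0.9698+0.0000i, 0.7167-0.5121i, 0.7167+0.5121i
```

The rank-3 fit on a noisy panel recovers the generating spectrum: the real
eigenvalue 0.9698 (truth 0.97) is the slow secular decline — about 3% of the
signal lost per year — and the conjugate pair carries the oscillation. All
moduli are inside the unit circle, so every mode decays:

```r
glance(fit)
#> # A tibble: 1 × 7
#>    rank     n     m numerical_rank energy_ratio max_modulus frac_inside_unit_circle
#>       3   200    21             20        0.998       0.970                       1
```

`energy_ratio = 0.998` says the rank-3 truncation retains 99.8% of the
squared singular-value mass of `X1`. The six-model comparison for the
held-out year 2021:

```r
fc <- forecast_all(panel, train_end = 2020,
                   grids = list(rf  = list(num_trees = 100, max_depth = 5),
                                gbm = list(num_trees = 100, interaction_depth = 3),
                                svm = list(cost = c(0.1, 1, 10), gamma = 0.1)),
                   seed = 1)
evaluate_models(fc)
#> # A tibble: 6 × 4
#>   model   rmse spearman     n
#> 1 rf      2.32    0.907   200
#> 2 dmd     2.32    0.905   200
#> 3 linreg  2.34    0.909   200
#> 4 svm     2.40    0.903   200
#> 5 gbm     2.87    0.896   200
#> 6 holt    5.28    0.677   200
```

RMSE is in rate units per 100,000 (the injected noise floor is 2), and
Spearman measures monotone agreement of the predicted county ranking with
the actual one. `autoplot(fit)` draws the eigenvalue spectrum on the unit
circle, `autoplot(rank_sweep(...))` the error/energy curves, and
`plot_comparison(fc)` the predicted-versus-actual overlay.
`dominant_mode_table(fit)` emits the per-county magnitude of the steady
mode, keyed by FIPS for mapping.

A thin command-line wrapper is installed at
`system.file("cli", "dmdcast.R", package = "dmdcast")` with subcommands
`simulate`, `fit-dmd`, and `compare` driven by a YAML config
(exit codes: 0 ok, 1 validation error, 2 runtime error).

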