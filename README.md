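# covermeta

Random-effects meta-analysis of paired cover-crop vs. bare-fallow field
comparisons, for agronomists and biogeochemists synthesising nitrate-leaching
and water-drainage literature.

Replacing winter fallow with a cover crop can cut nitrate leaching from
croplands substantially, but the primary literature is heterogeneous — few
replicates, missing variances, many species, soils and managements. This
package implements the complete synthesis pipeline for such data:

* **Effect size**: the log response ratio `ES = ln(X̄_CC / X̄_NCC)`, weighted by
  the nonparametric variance `v = (n_CC + n_NCC)/(n_CC · n_NCC)` so that
  studies reporting only replicate counts are still usable (`n = 1/1` gives
  `v = 2`).
* **Pooling**: DerSimonian–Laird `τ²`, random-effects weights `1/(v + τ²)`,
  normal-theory CIs, and back-transformation to percent change
  `100·(e^ES − 1)`.
* **Heterogeneity**: Cochran's `Q`, `I² = max(0, (Q − df)/Q)·100`, and the
  additive subgroup partition `Q_overall = ΣQ_within + Q_between` across
  moderator levels (cover-crop family/genus, soil order, soil texture, main
  crop, tillage), with the ≥3-articles-per-level inclusion rule.
* **Publication bias**: Begg–Mazumdar rank correlation (tie-corrected
  Kendall tau-b with continuity correction) plus funnel-plot data export.
* **Meta-regression**: single-covariate random-effects regression (rainfall,
  temperature) with `τ²` by restricted maximum likelihood.
* **Synthetic data**: a generator that draws observation tables under exactly
  the assumed model, with known truth, so every stage is verifiable
  end-to-end (`simulate_observations()`, `recovery_report()`).

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_funnel()` graphics.

## Worked example

```r
library(covermeta)

# a synthetic literature: 41 articles, ~1100 paired comparisons
obs <- simulate_observations(sim_config(seed = 2026))
run <- run_analysis(obs)
run
#> <cc_analysis> response: nitrate_leaching
#>   overall: k = 1110  ln(R) = -0.8516  ( -57.3 % change)  I2 = 35.5 %
#>   moderators analysed: cc_family, cc_genus, soil_order, soil_texture, main_crop, tillage
```

The overall pooled log ratio −0.85 says cover crops reduced nitrate leaching
by 57% in this synthetic literature; `I² = 35.5%` says about a third of the
observed spread is true heterogeneity rather than sampling noise. The
family-level moderator table mirrors the classic published layout:

```r
tidy(run$tables$cc_family) |>
  dplyr::select(level, n, Q, df, p_hetero, I2, es, pct_change)
#>   level             n      Q    df p_hetero    I2     es pct_change
#> 1 Asteraceae       18   31.7    17 1.66e- 2  46.3  0.185       20.3
#> 2 Brassicaceae    274  405.    273 3.46e- 7  32.6 -1.36       -74.3
#> 3 Leguminosae      89  125.     88 6.02e- 3  29.5 -0.503      -39.5
#> 4 Multigenera     100  147.     99 1.31e- 3  32.5 -0.772      -53.8
#> 5 Poaceae         629  894.    628 1.23e-11  29.8 -0.726      -51.6
#> 6 Total within     NA 1603.   1105 5.23e-21  NA   NA           NA
#> 7 Total between    NA  116.      4 3.84e-24  NA   NA           NA
#> 8 Overall        1110 1719.   1109 3.93e-29  35.5 -0.852      -57.3
```

The generator's truth set Brassicaceae at a 75% reduction and Poaceae at
52%; the pipeline recovers −74.3% and −51.6%. The `Total within` and
`Total between` rows add exactly to the overall `Q` (1603 + 116 = 1719): the
between row, on 4 df, is the heterogeneity the family moderator explains.
Publication bias and climate effects:

```r
eff <- compute_effects(obs)
begg_mazumdar(eff)
#> Begg-Mazumdar rank correlation (k = 1110)
#>   Kendall tau = 0.0248  z = 0.956  two-tailed p = 0.339
#>   |tau| < 0.20: no evidence of publication bias

fit_meta_regression(eff, "rainfall_mm")
#> Random-effects meta-regression (REML), k = 1110
#>   covariate: rainfall_mm  tau2 = 0.4759
#>   term                estimate       se    ci_low  ci_high statistic        p
#>   intercept           -1.81    0.111    -2.03     -1.59       -16.3  1.34e-59
#>   slope (rainfall_mm)  0.00111 0.000121  0.000872  0.00134      9.19 3.99e-20
#>   Q_model = 84.42  df = 1  p = 3.99e-20
```

The recovered rainfall slope (0.0011 per mm; truth 0.001) means cover crops
lose about 0.001 of log-ratio efficacy per extra mm of annual rainfall.
`autoplot(run$tables$cc_family)` draws the forest plot, `plot_funnel(eff)`
the funnel.

Real tables are read with
`read_observations("obs.csv", response = "nitrate_leaching")`, which applies
the row inclusion rules (positive means, `n = 1` imputation for blank
replicate counts) and records a validation report. A thin command-line
wrapper is included (`inst/scripts/covermeta`; see `?cc_cli`) with
`analyze`, `bias`, `metareg` and `simulate` subcommands, each writing CSVs
plus a reproducibility manifest.

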