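---
title: "Methods: random-effects meta-analysis of cover-crop leaching effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-effects meta-analysis of cover-crop leaching effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(covermeta)
library(dplyr)
```

## The problem and the model

Field experiments comparing a winter cover crop (CC) against bare fallow
(NCC) report treatment and control means of nitrate leaching
(kg N ha^-1^) or water drainage (mm), usually with few replicates and
often without any dispersion estimate. To synthesise such literature, each
paired comparison is summarised by the log response ratio

$$ES_i = \ln R_i = \ln\!\left(\frac{\bar X_{CC,i}}{\bar X_{NCC,i}}\right),$$

which is unit-free and symmetric around zero; negative values mean the
cover crop reduced the response. Because many primary studies omit
variances, every study is weighted by a *nonparametric* variance that
depends only on the replicate counts,

$$v_i = \frac{n_{CC,i} + n_{NCC,i}}{n_{CC,i}\, n_{NCC,i}},$$

so a single-report comparison (`n = 1/1`) carries $v = 2$ and four-replicate
plots carry $v = 0.5$. This is a deliberate trade: the weights reflect
replication effort, not the (unknown) sampling variance, and all downstream
inference is conditional on that convention.

True effects are assumed to vary across observations — different species,
soils, seasons — so pooling uses the random-effects model: observation
$i$'s true effect is $\theta_i = \mu + u_i$ with
$u_i \sim N(0, \tau^2)$, and the pooled estimate weights each record by
$w_i^* = 1/(v_i + \tau^2)$. The between-observation variance $\tau^2$ is
estimated by the DerSimonian–Laird moment estimator from Cochran's
$Q = \sum_i w_i (ES_i - \overline{ES})^2$ (fixed weights $w_i = 1/v_i$),
truncated at zero. Heterogeneity is expressed as

$$I^2 = \max\!\left(0,\ \frac{Q - df}{Q}\right) \times 100,$$

the percentage of observed variation beyond what sampling error alone
would produce; it is exactly 0 whenever $Q \le df$. Because the $Q$ test
has low power, its p-value is conventionally read against .10 (the
`hetero_alpha` setting, recorded in every run's configuration).

Pooled results are back-transformed to percent change,
$100\,(e^{ES} - 1)$, so a pooled ratio of 0.31 reads as a 69% reduction.

## Subgroup (moderator) partition

For a categorical moderator (cover-crop family or genus, soil order, soil
texture, main crop, tillage), the fixed-weight heterogeneity is additive:

$$Q_{\text{overall}} = \sum_g Q_g + Q_{\text{between}},$$

where $Q_g$ is computed within level $g$ and $Q_{\text{between}}$ (on
`levels - 1` df) measures how much heterogeneity the moderator explains.
`subgroup_partition()` reports this layout — per-level rows, "Total
within", "Total between", "Overall" — and the identity holds to machine
precision, which the test suite asserts at 1e-9 relative tolerance.

Two design choices were genuinely open:

* **Per-level τ².** Each level gets its own DerSimonian–Laird estimate by
  default, because published moderator tables report level-specific $I^2$,
  implying level-specific heterogeneity handling. A `tau2_mode = "pooled"`
  switch instead solves one moment equation across levels (residual $Q$
  against residual df and $\sum C_g$) and applies the common estimate to
  every level.
* **Between-group test by subtraction.** $Q_{\text{between}}$ is obtained
  as $Q_{\text{overall}} - \sum_g Q_g$ with fixed-effect weights, which is
  what makes the published tables' rows add up; it is not a
  random-effects Wald contrast.

A moderator level only enters if it is supported by at least three
distinct articles, and at least two levels must survive
(`filter_moderator_levels()`); rows with a missing moderator value are
kept for the overall analysis and excluded from that moderator's table
only. Missing values are represented as `NA` rather than a sentinel
string. When `article_id` is absent the support rule degrades, with a
warning, to counting observations.

## Publication bias

The Begg–Mazumdar rank-correlation test asks whether effect sizes drift
with study precision. Each effect is standardized as
$t_i = (ES_i - \overline{ES})/\sqrt{v_i - 1/\sum w}$ (fixed-effect mean;
the subtraction removes the variance already absorbed by the pooled mean),
and Kendall's rank correlation between $t_i$ and $v_i$ is computed.
Two numerical choices matter here:

* **tau-b, not tau-a.** With nonparametric variances, ties are pervasive
  (every `n = 1/1` row has $v = 2$), so the tie-corrected denominator is
  required for the statistic to stay in $[-1, 1]$ and behave sanely.
* **Continuity correction.** The normal approximation uses the score
  $S$ with null variance $k(k-1)(2k+5)/18$ and $|S|$ reduced by 1, the
  standard construction. When *all* variances are tied the correlation is
  undefined and reported as 0 with a warning.

An absolute tau below 0.20 is flagged as no evidence of bias.
`funnel_data()` exports the (ES, SE) pairs with fixed- and random-effects
reference lines for funnel inspection; `plot_funnel()` draws it.

## Meta-regression

For a numeric covariate (mean annual rainfall in mm, air temperature in
°C), `fit_meta_regression()` fits
$ES_i = \beta_0 + \beta_1 x_i + u_i + \varepsilon_i$ with
$u_i \sim N(0, \tau^2)$ and $\varepsilon_i \sim N(0, v_i)$. $\tau^2$ is
estimated by restricted maximum likelihood: the restricted log-likelihood
is profiled over the coefficients and maximised by bounded
one-dimensional search over $[0, 10\,\mathrm{Var}(ES)]$ with tolerance
1e-8 — for a single covariate this is more robust than general-purpose
multivariate optimisation, and the test suite verifies the optimum
against an explicit τ²-grid evaluated at 1e-4 resolution. Coefficients
are weighted least squares at the REML τ²; tests use the normal (z)
reference by default, with the Knapp–Hartung adjustment (scaled
covariance, t on $k - 2$ df) behind a flag. `Q_model` is the Wald
chi-square of the slope on 1 df. Covariates are used uncentred, so the
intercept is the predicted log ratio at covariate zero; slope estimates
are unaffected by centring (asserted as a test). Rows missing the
covariate are dropped for that regression only. At least three records
and two distinct covariate values are required — with exactly two design
points the fit is saturated and the line passes through the weighted
group means.

## What the synthetic generator emulates — and what it does not

`simulate_observations()` draws observation tables under exactly the
model the analysis assumes, so every stage can be verified against known
truth without any literature extraction. Per observation: moderator
levels are drawn independently from configured level probabilities
(genus nested within family), the true effect is the sum of level means
plus centred covariate terms plus $N(0, \tau^2)$ noise, and the observed
treatment mean is the control mean (log-normal) times
$e^{\theta_i} e^{\varepsilon_i}$ with
$\varepsilon_i \sim N(0, v_i)$ — the sampling noise matches the weight
the pipeline will assign the row.

The default configuration mirrors the marginal structure of a global
cover-crop nitrate-leaching synthesis: 41 articles contributing 20–34
observations each (~1100 rows), family shares dominated by Poaceae, mean
family ratios from 0.25 (Brassicaceae) to 1.0 (Asteraceae), about 60% of
rows with single-replicate means, heterogeneity $\tau^2 = 0.3$, rainfall
uniform on 300–1400 mm with slope 0.001 per mm, temperature 4–18 °C with
slope −0.009 per °C. Heterogeneity is injected at the observation level,
not the article level, matching the independence treatment of multiple
observations per article; an `article_sd` option adds an article-level
random effect for sensitivity studies but is off by default.

What passing recovery tests therefore shows is *internal consistency*:
the pipeline recovers the parameters of its own assumed model. Real
extracted literature differs in ways the generator does not emulate —
within-article correlation, moderators confounded with each other and
with climate, non-log-normal baselines, selective reporting — so
recovery results bound implementation error, not real-world validity.
`recovery_report()` compares estimated level percent changes (marginal
over the other, independently drawn moderators), within-level τ², and
covariate slopes against the generating configuration.

## Numerical conventions and edge cases

* $I^2$ and $\tau^2$ truncate to exactly 0 when $Q \le df$; $I^2 = 0$ at
  $Q = 0$.
* A single record: $Q = 0$, $df = 0$, $p_{hetero} = 1$, $\tau^2 = 0$,
  pooled SE $= \sqrt{v}$.
* Confidence intervals use the normal multiplier (1.95996 at 95%)
  throughout; no small-sample adjustment is applied to pooled means.
* No small-sample bias correction is applied to $\ln R$.
* Blank replicate counts are imputed as 1 (the convention for studies
  reporting only an overall mean) and counted in the validation report;
  non-positive means are rejected row-wise since $\ln R$ is undefined.
* Replicate-count arithmetic is done in double precision (large counts
  would overflow integer multiplication).
* Result CSVs render numerics to 6 significant digits and are
  byte-deterministic for identical inputs.

## Problem sizes used in the shipped checks

The package's simulation-based checks use sizes chosen to make
Monte-Carlo error small relative to the tolerances they assert: ~2000
observations for family-level percent-change recovery (±3 points), 2000
replicates at $k = 50$ for DL bias (|bias| < 0.05), 2000 replicates at
$k = 30$ for 93–97% interval coverage, 500 replicates at $k = 500$ for
slope recovery within two standard errors, and 2000 null replicates at
$k = 40$ for the rank test's size (3–7% at α = .05).

## Known limitations

* The nonparametric weights ignore reported variances even where a study
  provides them; the schema carries no per-row variance column.
* Observations from the same article are treated as independent; no
  robust (cluster) variance estimation is provided.
* Only single-covariate meta-regression is implemented — no interactions,
  no multi-covariate models, no permutation tests.
* Publication-bias assessment is rank-correlation only (no Egger
  regression, trim-and-fill, or selection models); funnel output is data,
  not a rendered figure, beyond the convenience `plot_funnel()`.
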