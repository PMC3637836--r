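---
title: "Clustering levels of linear growth: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering levels of linear growth: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levelmix)
```

## The model and its assumptions

`levelmix` models a balanced panel `Y_it` (`i = 1..n` areal units,
`t = 1..T` equally indexed time points) as straight lines with a **shared
slope** and a **latent level**: within unobserved component `j`,

$$Y_{it} = \alpha_j + \beta t + \epsilon_{it}, \qquad
\epsilon_{it} \sim N(0, \sigma^2) \text{ i.i.d.}$$

Marginally each unit's trajectory is a `J`-component finite mixture of
multivariate normals with diagonal covariance.  This is nonparametric
random-intercept modelling: the random-effect distribution is estimated as
a discrete distribution on `J` support points rather than assumed normal.
The assumptions that matter:

* **Balance.**  Every unit is observed at every time point.  All M-step
  denominators contain `T`; unbalanced input is rejected by `as_panel()`
  rather than imputed.
* **Conditional independence in time.**  Within a component, the `T`
  repeated observations are independent.  Serial correlation is assumed to
  be absorbed by the random intercept; the package deliberately does not
  fit unstructured covariance matrices.
* **Common slope (default).**  Clusters differ in level only.  A direct
  consequence, useful as a self-check: at any EM fixed point the common
  slope equals the pooled least-squares slope of all `n*T` points, so the
  estimated slope is identical for every `J`.  The package asserts this
  in its tests and it holds on every fitted dataset.

Extensions via `model_spec()`: component-specific slopes (`beta_j`),
component-specific variances (`sigma_j^2`), and a quadratic time term with
a common curvature, testable against the linear model with `lrt_nested()`.
The per-component-slope update and the per-component-variance update are
the obvious weighted analogues of the common-parameter formulas; the
quadratic case solves the 2x2 normal equations for slope and curvature
jointly.  Combining per-component slopes with a quadratic term is not
offered — the update for that combination is not defined anywhere we
trust, and the linear-in-`t` model is the substantive default.

## Estimation

The EM alternates responsibilities (`e_step()`, Bayes' rule in log space
with per-row log-sum-exp) and closed-form updates (`m_step()`).  Tunable
parameters, all in `em_control()`:

* `tol` (default `1e-4`): convergence is declared when the maximum
  absolute change of *any* parameter (weights, intercepts, slope(s),
  variance(s), curvature) between cycles drops below `tol`.  Only
  parameters are monitored, not responsibilities.
* `max_iter` (default `10000`): a non-converged fit is returned with
  `converged = FALSE` and a warning, never silently.
* `order`: with `"refreshed"` (default) each M-step formula consumes the
  newest values — intercepts from the old slope, slope from the *new*
  intercepts, variance from both new — which makes the EM a genuine
  coordinate ascent with provably non-decreasing observed likelihood (the
  test suite asserts monotonicity per iteration at tolerance 1e-8).  The
  `"literal"` mode updates every parameter from the previous cycle
  throughout; it usually converges to the same fixed point but carries no
  monotonicity guarantee, and is retained for fidelity experiments.
* `n_starts` (default 1): the default start is deterministic; additional
  starts perturb the starting intercepts with seeded normal noise
  (scale = half the spread of the per-unit OLS intercepts) and the best
  final likelihood wins.  One start suffices on well-separated data; the
  tiny-instance oracle tests use 4.

Starting values come from per-unit OLS lines: starting intercepts are the
empirical quantiles of the per-unit intercepts at probabilities
`j/(J+1)`, `j = 1..J`, with linear interpolation (R's type-7 quantile).
This convention reduces to the median at `J = 1`, consistent with the
median starts for slope and variance.  "The j-th quantile" admits several
readings; this one was chosen for that internal consistency.  The
per-unit residual variances use the maximum-likelihood denominator `T`
(not `T - 2`) to match the mixture variance's own definition, and the
starting variance is floored at `1e-8` so a perfectly linear panel still
has a usable start.

### Numerical safeguards

* Component densities are never formed as products of `T` normal
  densities: with `T = 21` and poor parameter values the product
  underflows; everything is summed in logs.
* The mixture likelihood is unbounded as `sigma^2 -> 0` when `J` is free.
  `J` is therefore always fixed during a fit and varied only across fits,
  and the variance update carries a hard floor of `1e-10` with a warning
  as a last-resort guard.
* A component whose total responsibility falls below `1e-10` has its
  parameters frozen for the cycle (warning emitted); the fit is not
  restarted and the parameter count `r` is left honest.
* MAP ties are broken toward the smaller component index.  Ties have
  measure zero for continuous posteriors, but tests need determinism.
* Components are reported in ascending-intercept order after every fit,
  which resolves label switching and makes runs comparable.

## Model choice and inference

`information_criteria()` counts free parameters as
`r = (#mean parameters) + (#variance parameters) + (J - 1)`; for the
default model `r = 2J + 1`.  Two criteria are computed:
`BIC = -2*loglik + r*log(n)` and `BIC2 = -2*loglik + r*log(nT)`.  Because
each areal unit — not each observation — is the clustered entity, `BIC`
(penalty `log n`) is the primary selection rule in `sweep_components()`;
`BIC2` is reported for completeness.  Their gap is identically
`r*log(T)`, which the test suite verifies against the bundled published
sweep table at all ten `J` values for both genders — this arithmetic is
also what pins down `r = 2J + 1`, which the source analysis never states
explicitly.

`pearson_chi_square()` uses the plain Pearson statistic: no Yates
correction, no pooling of sparse cells.  That exact convention reproduces
the published statistic 18.4645 (df 6, p 0.00517) on the men's 2x7
rural/urban table, which contains a zero cell and several small expected
counts.  Columns (or rows) with a zero margin are dropped with a warning
and the degrees of freedom count only occupied classes — matching the
published df = 6 for 7 classes in 2 rows.  On the women's table the
statistic is 15.3361 with df 6, giving p = 0.0178; the published p-value
of 0.00178 is inconsistent with its own statistic and df (a slipped
decimal) and is deliberately not reproduced.

## What the simulator emulates — and what it does not

`simulate_panel()` draws exactly from the generative model: latent labels
from the weights, then line-plus-independent-normal-noise trajectories.
Defaults mirror the motivating study's geometry (`n = 54`, `T = 21`), and
`nrw_mixture_params()` supplies the published J = 7 estimates (weights
renormalised from their printed 4-decimal rounding to sum to one) so the
whole pipeline can run without the undeposited original data.

Real regional data differ from these draws in ways the model ignores:
spatial correlation between neighbouring districts, serial correlation
beyond the shared level, heteroscedasticity over time, and outcome values
that are themselves estimates (life-table outputs) with their own
sampling error.  Passing recovery tests on simulated panels therefore
demonstrates the *estimator's* correctness at the published parameter
values, not that the model captures every feature of real data.

`recovery_study()` is the harness: replicate panels, refits at the true
`J`, ascending-intercept alignment (adequate because generating
intercepts are distinct by construction; optimal matching is not needed),
per-parameter bias/RMSE, MAP-vs-truth label agreement, and optionally the
frequency with which BIC selects the true `J`.  Replicate `r` uses seed
`master*1000 + r`, recorded in the report.

A note on what recovery at the published truth can show: with the
published overlap between adjacent levels (gaps of 0.3–0.8 outcome units
against a residual standard deviation of about 0.4), individual
intercepts and weights are recovered noisily and MAP labels are not
always unique on simulated draws — the slope and variance, which pool
across the whole panel, are recovered tightly (slope to ±0.01, variance
to ±0.02 over 10 replicates) and are the quantities the acceptance
script reports.  The variance shows a small upward drift relative to the
generating value because overlapping components share responsibility for
each trajectory; it stays well inside the stated tolerance.

## Problem sizes

The test suite and acceptance script run the study-sized experiments at
their natural size — 10 replicates of `n = 54`, `T = 21`, `J = 7` fits
take a couple of seconds — and use `n <= 5`, `T <= 4` instances for the
brute-force likelihood oracle, where direct numerical maximisation of the
observed mixture likelihood from a grid of starts is feasible and EM must
match it to 1e-6.  Selection-consistency checks use `n = 100`, `T = 21`
with three well-separated components.

## Known limitations

* No spatial smoothing or spatially correlated noise (a conditional
  autoregressive treatment is a different modelling philosophy: smoothing
  rather than clustering).
* No parametric (normal) random-effects comparison fit; `lrt_nested()`
  compares specifications fitted by this package only.
* Delimited text input only; classification and parameter tables are
  exported as CSV for external mapping tools rather than rendered as
  choropleths.
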