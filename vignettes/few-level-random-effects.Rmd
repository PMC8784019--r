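---
title: "Fixed or random effects with few grouping levels: the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed or random effects with few grouping levels: the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fewlevels)
```

## The question

A widely repeated guideline holds that a grouping factor should have at
least five levels before it is modelled as a random effect. The guideline
is about the *among-group variance*: with two or three draws from the
group distribution, its variance is genuinely hard to estimate. But in
much applied work the grouping factor is a nuisance — sites, enclosures,
individuals — included only to absorb non-independence, while scientific
interest is in the fixed-effect slopes. `fewlevels` provides the machinery
to ask, by simulation, whether *slope* estimation and its uncertainty
actually degrade when a random intercept has fewer than five levels, by
fitting both candidate models to the same simulated datasets.

## Generating model

Each dataset is drawn from

$$y_i = \mu + \mathrm{Site}_{j(i)} + \beta_1 x_{1i} + \beta_2 x_{2i}
  + \varepsilon_i, \qquad
  \mathrm{Site}_j \sim N(0, \sigma^2_{\mathrm{site}}), \quad
  \varepsilon_i \sim N(0, \sigma^2_\varepsilon).$$

Defaults (see `scenario_config()`): $\mu = 73$ (an arbitrary grand mean on
a tree-height-like scale), a strong slope $\beta_1 = 2$ and a weak slope
$\beta_2 = 0.2$, unit site and residual variances, and predictors
$x_1, x_2 \sim N(0, 0.5)$, mimicking covariates standardized to roughly
half-unit spread. The strong/weak pair puts one slope an order of
magnitude above the other so that metrics can be compared across
signal-to-noise regimes; with variance 0.5 on $x_1$ the marginal response
variance decomposes as $1 + 2^2(0.5) + 0.2^2(0.5) + 1 = 4.02$, i.e. the
site effect, the strong slope and the noise each contribute comparably.
(One could also read "scaled by two standard deviations" conventions as
implying variance 0.25; the generator follows the stated variance of 0.5.)

**Unbalanced allocation.** `allocate_groups()` gives every level one
observation, assigns the remaining $n - J$ uniformly at random with
replacement across the $J$ levels, and rejects-and-redraws any allocation
whose counts come out all equal. Uniform assignment is the minimal reading
of "randomly selected levels"; rejection re-draws the entire allocation
rather than repairing it by a swap, which keeps the accepted distribution
exactly the conditioned multinomial law (verified in the tests against an
independent multinomial oracle). Balanced designs are excluded on purpose:
there the fixed-effect estimators are independent of the random effects,
so including them would dilute the contrast under study. Perfect balance
is only possible when $J \mid n$; otherwise the rejection loop provably
accepts the first draw. The degenerate configurations $n \le J$ (where
rejection could never terminate) and $J = 1$ are refused at construction.

## The two estimators

**LM.** `fit_lm()` runs OLS on intercept + $x_1$ + $x_2$ + treatment-coded
group dummies; slope CIs use $t$ quantiles with $n - J - 2$ residual
degrees of freedom. This is the classical "no pooling" treatment of the
blocking factor.

**LMM.** `fit_lmm()` estimates the random-intercept model by REML. The
criterion is profiled to one dimension through
$\theta = \sigma_{\mathrm{site}} / \sigma_\varepsilon$: with
$V(\theta) = I + \theta^2 ZZ^\top$,

$$-2\,\ell_R(\theta) \;\doteq\; \log\det V
  + \log\det\!\big(X^\top V^{-1} X\big)
  + (n - p)\,\log\!\big(r^\top V^{-1} r\big),$$

up to an additive constant, where $r$ is the GLS residual and $p = 3$.
Because $V$ is block diagonal in the groups, $V^{-1}$ has the closed
Woodbury form $I - \tfrac{\theta^2}{1 + \theta^2 n_j}J$ within a group of
size $n_j$, so one criterion evaluation costs $O(n)$; `reml_criterion()`
exposes it directly. Profiling makes the boundary explicit and the
problem, in practice, unimodal in $\theta$.

**Optimization and numerical choices.**

- The minimizer bracket $[0, u]$ is grown geometrically ($u \to 2u$, capped
  at $10^6$) until the criterion increases, then Brent search
  (`optimize`, tol $10^{-8}$) runs on it.
- The boundary value $\theta = 0$ is compared explicitly against the
  interior optimum; ties (within $10^{-9}$) resolve to the smaller
  $\theta$, i.e. toward the boundary.
- A fit with $\hat\theta$ below the **singularity tolerance** ($10^{-4}$ on
  the ratio scale, the de facto standard in mixed-model software;
  configurable) is flagged singular: the random-effect variance is
  estimated at, or numerically at, zero.
- Design matrices are rank-checked on their singular values with relative
  tolerance $10^{-10}$; rank-deficient designs error, naming the column.
- $\hat\sigma^2_\varepsilon = r^\top V^{-1} r / (n - p)$ at the optimum and
  $\hat\sigma^2_{\mathrm{site}} = \hat\theta^2 \hat\sigma^2_\varepsilon$;
  the fixed-effect covariance is
  $\hat\sigma^2_\varepsilon (X^\top V^{-1} X)^{-1}$.

Two structural identities pin the fitter down at its extremes and are
asserted in the tests: at $\theta = 0$ the GLS slopes equal pooled OLS
(full pooling), and as $\theta \to \infty$ they converge to the
dummy-coded LM slopes (no pooling; `slopes_at_infinite_variance()`
computes the limit by within-group centering). Partial pooling lives
between these poles.

**Interval policy.** How the original analyses computed LMM intervals is
not something a reimplementation can observe, so the policy is an explicit
configuration rather than a claim: the default is Wald with
standard-normal quantiles — the ubiquitous default for mixed models, and
the choice that reproduces the observed undercoverage at $N = 30$ — with a
$t$ alternative (df $= n - 3$) available via `ci_method`. The LM always
uses exact $t$ intervals. The policy in force is recorded in the run
metadata. Profile-likelihood and bootstrap intervals are out of scope.
Fixed-effect p-values are not computed; the evaluation uses CIs only.

## Metrics

For each cell × model × parameter, `summarize_records()` reports: coverage
of the 95% CIs (endpoints count as covered — a measure-zero convention
fixed for determinism), **relative RMSE** defined as
$\sqrt{\mathrm{mean}((\hat\beta - \beta)^2)}\,/\,|\beta|$ (the
normalization by the true value makes the $\beta = 2$ and $\beta = 0.2$
panels comparable; it is refused for a true value of zero), bias and mean
estimate, the empirical 0.025/0.975 quantile interval (linear
interpolation of order statistics, R's type 7 — other definitions shift
the interval endpoints slightly), and the singular-fit proportion.
Summaries can be stratified by singular-fit status; a stratum with no
usable replicates is omitted and a stratum with exactly one is flagged,
since a single 0/1 outcome cannot stand in for a Monte Carlo mean.
Non-converged fits are excluded from the metrics and disclosed in an
`n_excluded` tally rather than silently redrawn — redrawing would bias the
Monte Carlo distribution (with this generator and fitter, failures do not
occur in practice).

## Orchestration and reproducibility

`experiment_plan()` describes the grid ($N \in \{30, 60, 120\} \times J
\in \{3, 5, 10\}$, 10,000 replicates per cell by default) and the
policies; `run_cell()` pairs the designs — LM and LMM always see the
*same* dataset, verified through per-dataset checksums in the records —
and `run_experiment()` stacks the cells into one tidy long-format table
(CSV canonical) plus summaries and a JSON metadata sidecar.

Randomness: one master seed spawns one L'Ecuyer-CMRG stream per cell
(`parallel::nextRNGStream`) and one substream per replicate
(`parallel::nextRNGSubStream`). Cells are therefore independent of
execution order and could run concurrently with identical results, and any
single replicate can be regenerated in isolation.

## Desk-scale replication

The full study is 90,000 datasets and 180,000 fits. The packaged
acceptance script and the test suite run a reduced but statistically
adequate profile: 2,000 replicates per cell (Monte Carlo SE on a coverage
of 0.95 is $\approx 0.005$, comfortably inside the ±0.02 band used for
the nominal-coverage check), with the full grid taking on the order of a
minute or two on a single CPU. `scripts/acceptance.R` recomputes, from
scratch at the largest design ($N = 120$, $J = 10$): the mean LMM
estimates of both slopes and the intercept, and the LM and LMM coverage of
the stronger slope. The qualitative grid-wide patterns — coverage driven
by $N$ rather than $J$, LMM undercoverage at $N = 30$, RMSE falling with
$N$, singular fits concentrating at few levels and small $N$, and the
random-effect variance recovered with widening quantile intervals as
levels shrink — are asserted property-style over the same reduced grid in
`tests/testthat/test-acceptance.R`.

## What the generator does and does not emulate

It emulates: Gaussian responses on an unbalanced block design, independent
standardized predictors, a single random intercept, and variance
components of equal magnitude. It does not emulate: non-Gaussian
responses, random slopes, correlated or group-confounded predictors,
heteroscedasticity, temporal or spatial autocorrelation within groups, or
group counts confounded with sample size. Conclusions from passing tests
are accordingly about this regime; in particular, a slope whose variation
is itself of interest, or predictors varying mostly between groups, could
behave very differently with few levels.

## Known limitations

- The REML profile is assumed unimodal in $\theta$; Brent search plus the
  explicit boundary comparison has matched a 1,000-point grid search on
  every tested dataset, but pathological multimodality is not excluded in
  general.
- Wald-z LMM intervals are anti-conservative in small samples by
  construction; that behaviour is part of what the study measures, not a
  defect, but it means the package's LMM coverage figures should not be
  quoted as properties of better small-sample interval methods
  (Satterthwaite, Kenward-Roger, profile).
- The singularity flag is a threshold on $\hat\theta$, so its proportion
  depends (weakly) on the chosen tolerance; the default matches the
  convention used by standard mixed-model diagnostics.
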