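---
title: "Two-level zero-inflated count models for daily smoking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level zero-inflated count models for daily smoking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zicmpreg)
```

## The modeling problem

Daily cigarette consumption in a general-population survey is a
non-negative count with two awkward features: the large majority of
respondents report zero (about 90% in the Khuzestan Daily Smoking
Consumption Survey that motivates this package), and the positive counts
are strongly overdispersed (pooled variance/mean ratio near 19).  A plain
Poisson regression fails on both.  The package therefore implements six
families — Poisson (P), negative binomial (NB), Conway–Maxwell–Poisson
(CMP), and their zero-inflated versions (ZIP, ZINB, ZICMP) — in a
two-level structure: respondents (level 1) nested in cities (level 2),
with independent normal random intercepts per city.

The zero-inflated mixture is

$$P(Y_{ij} = y) = \phi_{ij}\,1\{y=0\} + (1-\phi_{ij})\,f(y \mid \theta_{ij}),$$

with a logit model for the structural-zero (non-smoker) probability and a
log link for the count-part rate:

$$\operatorname{logit}(\phi_{ij}) = \xi_{ij} = a_{ij}^T\alpha + w_i, \qquad
\log \lambda_{ij} = \eta_{ij} = b_{ij}^T\beta + u_i,$$

where $w_i \sim N(0, \sigma_w^2)$ and $u_i \sim N(0, \sigma_u^2)$ are
independent city effects.  Non-zero-inflated models have no zero part and
carry only $u_i$.  Exponentiated coefficients are reported as odds ratios
(zero part) and rate ratios (count part), with reference categories at
exactly 1.

## The CMP family

The CMP pmf is $P(Y=y) = \lambda^y (y!)^{-\nu} / Z(\lambda,\nu)$ with
normalizer $Z(\lambda,\nu) = \sum_{i\ge 0} \lambda^i (i!)^{-\nu}$.  It
nests the Poisson ($\nu = 1$), is overdispersed for $\nu < 1$ and
underdispersed for $\nu > 1$; $\nu = 0$ is admitted only with
$\lambda < 1$, where the series is geometric — otherwise it diverges and
construction fails with an explicit error.  The package uses the rate
parameterization ($\lambda$, $\nu$) exactly as written above; a
mean-parameterized CMP is deliberately out of scope, because published
estimates from other software do not always state which parameterization
they use and the rate form is the one with an unambiguous definition.

Everything is computed in log space.  The normalizer is a streaming
log-sum-exp over blocks of 256 series terms; summation stops when terms
are decreasing and the current term is below `rel_tol` (default `1e-12`)
of the running sum, with a hard cap of $10^6$ terms that raises an error
rather than silently truncating (the cap is reachable only when
$\lambda^{1/\nu}$ is on the order of $10^6$, far outside the data range
of this application).  Moments use the same truncation discipline on the
$y$- and $y^2$-weighted sums, and sampling inverts the exact cdf on the
truncated support, which makes draws reproducible from a seed.

## Marginal likelihood and estimation

The marginal likelihood integrates the city effects out cluster by
cluster.  Because cluster sizes in the target design range from 5 to 235,
the integrand can be extremely peaked, so a fixed Gauss–Hermite rule
centered at zero would be inaccurate; the package uses *adaptive*
Gauss–Hermite quadrature: per cluster it locates the posterior mode of
$(w, u)$, measures the curvature there with finite differences, and
shifts/scales the product rule accordingly.  `K = 15` nodes per dimension
is the default; in our convergence checks the value is already stable to
well below $10^{-6}$ by `K = 5` on survey-sized problems, which is what
the replicate simulations below use.  `K = 1` with mode shifting is the
Laplace approximation and is available as a fast option.

Optimization runs on unconstrained scales — coefficients directly,
dispersion and both SDs as logs — with `nlminb` and finite-difference
gradients, started from fixed-effects GLM fits that ignore clustering
(logistic regression of the zero indicator, Poisson regression of the
positive counts) with SDs started at 0.1.  Additional jittered starts are
available; ties are broken by the highest log-likelihood.  Convergence is
declared when the optimizer reports success and the gradient max-norm is
small relative to the log-likelihood scale.  Random-effect SDs are
allowed to collapse towards zero; the fit reports the boundary (standard
errors there come out `NA` from the singular information matrix) and does
not silently refit without the random effect, since a boundary estimate
is itself informative.

Standard errors are square roots of the inverse observed information
(numerical Hessian of the negative marginal log-likelihood), with
log-scale parameters transformed back by the delta method.  Significance
tiers follow the conventional 0.05 / 0.01 / 0.001 footnoting.

## Model comparison

`fit_indices()` reports $P$ (free-parameter count), log-likelihood,
deviance $D = -2\,\mathrm{LL}$, $\mathrm{AIC} = -2\,\mathrm{LL} + 2P$,
$\mathrm{BIC} = -2\,\mathrm{LL} + P\ln n$ with $n$ the number of
*observations* (1,973 in the target survey — this convention, not the
cluster count, is the one that reproduces the published index table), and
MSE of the fitted means.  The survey's published comparison table leaves
the MSE definition unstated; the package uses conditional fitted means at
the per-cluster empirical-Bayes modes, the conventional choice for
multilevel fits, and exposes `mse_type = "marginal"` as the plug-in
alternative.  `rank_models()` ranks per index and picks the overall
winner by AIC with a BIC tiebreak, flagging any disagreement between
indices rather than hiding it.

## The synthetic survey generator

The raw survey microdata are not public, so `dscs_config()` +
`simulate_dscs()` emulate the study design: 29 city clusters with the
published sizes (total 1,973), each categorical covariate drawn
independently from its published marginal, and the response generated
from the two-level ZICMP model with the published two-part effect
estimates as true coefficients, $\nu = 0.38$, and
$\sigma_w = \sigma_u = 0.2$.  The SDs are set at 0.2 rather than the
published near-zero boundary estimates precisely so that recovery tests
exercise the integration machinery instead of a degenerate special case.

Two generator choices deserve comment.  First, the published effect table
contains no intercepts; the defaults $\alpha_0 = 3.5$ and
$\beta_0 = -0.30$ were calibrated once by simulation so that the default
emulator's zero fraction is centered on the survey's 90.1% (it stayed
inside 88–92% across 20 calibration seeds) and the positive counts sit at
a plausible smoker scale.  With the rate-parameterized CMP the published
effects imply a heavier upper tail than the survey's observed maximum
(single simulated respondents can reach counts above 100); the intercept
trades the smoker mean (about 7.6 cigarettes/day simulated versus 10.6
observed) against that tail.  Second, covariates are sampled
independently because only marginals are published; this ignores real
associations (e.g., "housewife" implies female), so the config accepts an
optional joint sex-by-occupation probability table when such impossible
cells matter.  City-level means are treated as emergent, not targeted:
jointly matching the per-city means and the covariate marginals would
over-determine the generative model.

What passing tests on these data do and do not show: they demonstrate
that the likelihood, quadrature and optimizer recover known truth under
the survey's size and zero-inflation structure; they cannot validate the
substantive published coefficient values, which would require the
non-public microdata.

## Numerical choices and test scales

Replicate simulations in the tests and the acceptance script use `K = 5`
(checked against `K = 15`/`K = 30`), survey-sized TL-ZIP batteries of 20
replicates with 10-replicate TL-ZINB/TL-ZICMP batteries, and a 20-seed
ZIP-versus-P AIC comparison on 12-cluster data; these are the package's
chosen problem sizes for routine verification, with the nominal
100-replicate coverage statement asserted under one-sided binomial slack
for the smaller batch.  The dense-grid integration oracle uses 20,001
trapezoid points over $\pm 8$ SD in one dimension and a $601^2$ grid in
two.  Screening tests in `group_summary()` use the uncorrected Pearson
chi-square on 2×2 tables (the convention that matches the survey's
published p-values) and Mann–Whitney / Kruskal–Wallis rank tests with
their large-sample p-values; they are descriptive conveniences and never
gate modeling.

## Known limitations

- Random intercepts only: no random slopes, crossed effects, or a third
  level.
- The CMP series cap makes extremely small $\nu$ combined with large
  $\lambda$ (i.e. $\lambda^{1/\nu} \gtrsim 10^6$) an error by design;
  the fitter treats such parameter regions as infeasible during search.
- Wald intervals near variance boundaries are unreliable (reported as
  `NA` when the information matrix is singular); no profile-likelihood
  intervals are provided.
- The generator's independence across covariates slightly distorts joint
  covariate distributions relative to any real survey.

## A worked example

```{r example, eval = FALSE}
cfg <- dscs_config(seed = 20230529)
d <- simulate_dscs(cfg)
city_summary(d)[1:3, ]
fit <- fit_model(d, model_spec("poisson", zero_inflated = TRUE), K = 5)
fit_indices(fit)
effect_table(fit)[1:6, ]
```
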