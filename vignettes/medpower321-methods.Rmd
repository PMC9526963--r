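---
title: "Power analysis for 3-2-1 multilevel mediation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for 3-2-1 multilevel mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medpower321)
```

## The design and the question

Cluster-randomized implementation trials commonly have three nested levels:
organizations (level 3) are randomized to an implementation strategy, the
strategy is hypothesized to change a provider-level mediator (level 2), and
the mediator in turn is hypothesized to change a patient-level outcome
(level 1). In this *3-2-1 mediation design* the scientific target is the
level-3 indirect effect — the product $a_3 b_3$ of the treatment-to-mediator
and mediator-to-outcome paths — and the planning question is: how many
organizations, providers per organization, and patients per provider are
needed for an acceptable chance (power $\ge 0.8$) of detecting it?

No useful closed form exists for the power of the indirect-effect test in
this design, so medpower321 answers the question by Monte Carlo simulation:
generate many datasets from the hypothesized population, fit the mediation
models to each, test $H_0: a_3 b_3 = 0$, and report the rejection rate.

## The generating model

A design is specified on a standardized scale: paths $a_3$, $b_3$, $c'_3$
(level 3), $b_2$ (level 2), and intraclass correlations $ICC_{m3}$ (share of
mediator variance between clusters) and $ICC_{y2}$, $ICC_{y3}$ (shares of
outcome variance at levels 2 and 3). `derive_components()` maps these to the
raw coefficients and variance components of a Gaussian random-intercept
model in which the total variances of $M$ and $Y$ are exactly 1 and the
treatment is coded $X \in \{-1, +1\}$ with exact 50/50 allocation (so
$\mathrm{var}(X) = 1$):

$$M_{jk} = a X_k + u_k + w_{jk}, \qquad
  Y_{ijk} = b_3^{raw}(aX_k + u_k) + c^{raw} X_k + e_{Bk}
          + b_2^{raw} w_{jk} + e_{2jk} + e_{1ijk}.$$

**Standardization metric.** The level-3 paths are standardized *between
level*: they are regression coefficients among the latent level-3 components
of $M$ and $Y$ after those components are scaled to unit variance, matching
multilevel-SEM conventions. The alternative — standardizing against total
variance — would require the level-3 explained variance of $M$ to reach
$a_3^2$ of the total; with $a_3 = 0.59$ and $ICC_{m3} = 0.2$ that exceeds
the entire level-3 share, leaving most interesting designs infeasible.
Under the between-level convention every cell of the package's default grid
is feasible, and the identity $\mathrm{var}(M) = \mathrm{var}(Y) = 1$ holds
exactly (this is asserted in the test suite for all 17,496 default cells).

**Defaults.** The default `design_grid()` covers small/medium/large path
values $\{0.14, 0.39, 0.59\}$ for $a_3$ and $b_3$, small/medium direct
effects $\{0.14, 0.39\}$, $b_2$ fixed at the medium value 0.39 (it is rarely
of substantive interest but must be non-zero for realism), ICCs
$\{0.05, 0.10, 0.20\}$ at each relevant level, and sample sizes
$N_3 \in \{10, 20, 40, 60\}$, $N_2 \in \{5, 10, 20\}$,
$N_1 \in \{3, 6, 12\}$ — values chosen to bracket what implementation
studies in healthcare settings can realistically enroll. Fully crossed this
gives $3^7 \cdot 4 \cdot 2 = 17{,}496$ designs. `n3` must be even so the
two arms are exactly balanced; an odd `n3` is rejected rather than silently
imbalanced.

**Location parameters.** Grand means are fixed at 0 in the generator
(location does not affect the power of the scale-free Sobel statistic);
intercepts are nonetheless estimated by both fitting routines.

## The two estimators

**MVM (manifest multilevel regression).** `fit_mvm()` fits, by maximum
likelihood, a 2-level random-intercept model for $M$ and a 3-level
random-intercept model for $Y$ using the centered-within-context
decomposition of the mediator: the observed cluster mean $\bar M_k$ enters
at level 3 and the deviation $M_{jk} - \bar M_k$ at level 2. Because the
observed cluster mean carries within-cluster sampling error, its slope is
attenuated toward $b_2^{raw}$: the large-sample value is

$$b_3^{manifest} =
  \frac{b_3^{raw}\,\tau_m + b_2^{raw}\,\sigma^2_w/n_2}
       {\tau_m + \sigma^2_w/n_2},$$

with $\tau_m$ the level-3 residual variance of $M$ and $\sigma^2_w$ its
within-cluster variance. The test suite verifies this limit by simulation.

On balanced data the nested design decomposes orthogonally into level-1
deviations, within-cluster contrasts of unit means, and cluster means; the
likelihood factors into independent Gaussian blocks and the ML solution is
available in closed form (blockwise OLS for the fixed effects, mean squares
for the variances, pooling of adjacent blocks when a variance component
hits its zero bound). This closed form is what makes full-grid sweeps
tractable; it is validated against `lme4::lmer(..., REML = FALSE)` —
estimates, standard errors, and log-likelihoods agree to numerical
precision — and lme4 remains the independent oracle in the tests, never the
engine. Standard errors are model-based ML information SEs; variance
components are ML (no REML correction), truncated at zero and flagged when
the unconstrained estimate is negative. A dataset whose cluster means of
$M$ are (numerically) constant makes the outcome model rank-deficient; the
fit is returned with `converged = FALSE` and the power engine excludes that
replication, mirroring how failed replications are handled in
simulation-based power software.

**MSEM-style latent decomposition.** `fit_msem()` estimates the level-3
paths on *latent* cluster components: unbiased method-of-moments estimates
subtract the within-cluster mean square over $n_2$ from the between-cluster
covariance matrix (`latent_between_cov()`), removing the sampling error that
attenuates the manifest regression. Standard errors come from a
nonparametric cluster bootstrap, stratified by arm and seeded. This is a
deliberate, transparent stand-in for full-information-ML multilevel SEM:
the estimand is identical (latent between-level paths), but the moment
estimator can return a negative latent variance in small samples — such
replications are flagged non-converged and excluded, analogous to the
convergence failures of likelihood-based MSEM. The moment-plus-bootstrap
route is noticeably less efficient than full-ML MSEM at small $n_3$ and
small $n_2$, where the subtraction is large relative to its sampling error
and the bootstrap distribution of the latent regression is heavy-tailed; so
while the qualitative ordering (unbiased but less powerful than MVM) is
reproduced faithfully, MSEM power values from this package at small
samples should be read as conservative relative to full-ML MSEM.

## The test

`sobel_test()` applies the first-order delta (Sobel) statistic
$z = \hat a \hat b_3 / \sqrt{\hat a^2 SE_b^2 + \hat b_3^2 SE_a^2}$ with
normal critical values (1.959964 two-sided, 1.644854 one-sided at
$\alpha = 0.05$; a boundary $z$ counts as rejection — a measure-zero
convention fixed for determinism). The one-sided decision is an algebraic
transformation of the stored two-sided $z$ (`one_sided_from_two()`), so
both sidedness results come from a single simulation pass. The hypothesized
direction defaults to $+1$, the sign of every effect in the default grid.
The Sobel test is asymptotic and slightly conservative under the null —
the suite checks that the type-I rate at $a_3 = b_3 = 0$ stays at or below
$\alpha$.

## The power engine

`estimate_power()` / `sweep_power()` run the replication loop. Two design
choices matter for speed and reproducibility:

* **Sufficient-statistic simulation.** Both estimators depend on the data
  only through each level-2 unit's mediator value and outcome mean and the
  level-1 residual sum of squares. The engine therefore simulates those
  statistics directly — unit means as Gaussians, the residual SS as a
  scaled $\chi^2$ — which is *exact* under the Gaussian model, not an
  approximation, and avoids materializing level-1 rows. A test confirms the
  power estimates agree with explicitly simulating and fitting full
  datasets.
* **Design-keyed substreams.** Each design derives its own RNG seed from
  the run seed and the design's field values. Results are therefore
  identical whatever the order, chunking, resumption, or worker count of a
  sweep, and any single design can be recomputed in isolation. Replication
  $r$ of a design is a fixed column of the design's vectorized draw rather
  than an independently seeded stream; reproducibility is at design
  granularity, which is the unit at which results are stored and compared.

Power is reported with completed replications in the denominator
(non-converged fits are excluded, and never counted as rejections), with
`reps_completed` exposed so the "out of requested" convention can also be
formed; a Monte Carlo standard error accompanies every estimate. The
default is 500 replications per design and an adequacy threshold of 0.8,
both parameters.

`summarize_power_marginals()` reproduces the design-frequency layout
(adequate counts by each characteristic's values and by total sample size);
`minimum_sample_sizes()` searches each effect-size/ICC cell for the
lexicographically smallest adequate $(N_3, N_2, N_1)$ — smallest $N_3$
first, since highest-level units are the costliest to recruit — collapsing
the $ICC_{y2}$ axis, and returns `NA` for cells where no combination
qualifies.

## Numerical and degenerate-input conventions

* Variance-component zero bounds: constrained ML by pooling the adjacent
  variance blocks, flagged via `truncated`; truncation does not invalidate
  a replication.
* Zero within-cluster mediator variance leaves $b_2$ undefined (`NA`) but
  the level-3 paths estimable; zero between-cluster variance of the
  mediator mean is a rank-deficient outcome model and is non-converged.
* With $n_1 = 1$ the level-1 and level-2 outcome variances are not
  separately identified; the level-1 variance is reported as 0 and their
  sum as the level-2 component.
* Singularity is declared at a relative determinant tolerance of
  $10^{-12}$; datasets are checked for exact balance before fitting.
* CSV round trips use 17 significant digits and `as.numeric()` parsing so
  stored datasets reproduce fits bit-for-bit.

## Problem sizes used by the shipped checks

The package's own validation uses desk-scale sizes chosen to keep the whole
suite comfortably reproducible on a single CPU: full-grid sweeps for the
headline adequacy counts run all 17,496 designs at 200 replications each
(Monte Carlo SE $\approx 0.028$ near power 0.8), consistency checks use
single large-sample datasets ($N_3$ up to 2000), the null-calibration check
uses 2000 replications, and targeted spot checks use the full 500
replications. The acceptance script rescales nothing else; all numbers it
prints are computed fresh from these runs.

## What the simulations do and do not establish

The generator matches the assumptions of the fitted models: Gaussian random
effects and residuals at every level, exactly balanced clusters, a binary
cluster-level treatment with perfect 50/50 allocation, no covariates,
constant variances across arms, and correctly specified mean structure.
Passing tests therefore demonstrate the internal consistency and
calibration of the machinery — they do not certify power for real data
with skewed or heteroscedastic outcomes, unbalanced clusters, missingness,
or misspecified mediation structure. Model-based ML standard errors are
used rather than sandwich (robust) corrections; under the correctly
specified generating model the two are asymptotically equivalent, but
small-sample sandwich behavior is one documented source of difference from
power figures produced by software using robust SEs — robust-SE power
tends to run slightly higher at small cluster counts because the sandwich
variance estimate is itself downward-biased there. Designs outside the
default grid (3-3-1 or 3-1-1 variable placement, unbalanced clusters,
binary outcomes, random slopes, moderated mediation) are out of scope.

## A worked planning example

```{r, fig.width = 6, fig.height = 4}
grid <- design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39,
                    icc_m3 = 0.2, icc_y2 = 0.1, icc_y3 = 0.2,
                    n3 = c(10, 20, 40, 60), n2 = c(5, 10), n1 = 6)
res <- estimate_power(grid, reps = 200, seed = 1)
res[, c("n3", "n2", "n_total", "power_two", "power_one", "mc_se_two")]
autoplot(res)
minimum_sample_sizes(res)
```
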