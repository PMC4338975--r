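---
title: "Analyzing phylogenetically paired designs with two-layer compound symmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing phylogenetically paired designs with two-layer compound symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phypairs)
```

## The design and the model

A phylogenetically paired design measures a trait on replicate individuals
of two closely related species per pair, one from each of two groups of
interest (here coded as origin: native = 0, invasive = 1). Replicates on a
species are exchangeable, and the two species of a pair share ancestry, so
the data carry two distinct correlation layers. The model fit by
`fit_pair_model()` is

$$y_{ijk} = \mu + \beta x_{ij} + \alpha_i + \gamma_{ij} + \varepsilon_{ijk},$$

with pair effects $\alpha_i \sim N(0, \tau^2)$, species-within-pair effects
$\gamma_{ij} \sim N(0, \omega^2)$ and errors
$\varepsilon_{ijk} \sim N(0, \sigma^2)$, all independent. The marginal
covariance is block-diagonal over pairs; within a block, diagonal entries
are $\tau^2+\omega^2+\sigma^2$, entries within one species
$\tau^2+\omega^2$, and entries across the two species $\tau^2$
(`pair_covariance()`). Equivalently, all correlations within a species equal
$\rho = (\tau^2+\omega^2)/(\tau^2+\omega^2+\sigma^2)$ and all correlations
across species within a pair equal
$\theta = \tau^2/(\tau^2+\omega^2+\sigma^2)$, so $0 \le \theta \le \rho < 1$
(`cs_correlations()`).

All parameters are in (squared) trait units; none has a default because
they are estimated. The two reference analyses are nested restrictions:
Model 2 forces $\omega^2 = 0$ (one correlation parameter must serve both
layers) and Model 1 forces $\tau^2 = \omega^2 = 0$ (independence).

### Assumptions

* exactly two species per pair, with opposite origin codes;
* replicates exchangeable within species (no time structure — compound
  symmetry would be wrong for longitudinal measurements);
* Gaussian effects and errors; homoscedastic residuals across species;
* pair effects iid across pairs *in the fitted model*. Real pairs are
  phylogenetically related, which is exactly the misspecification the
  simulator reproduces (below).

## Estimation

Variance components are estimated by REML over the non-negative orthant,
fixed effects by GLS at the REML estimates.

**Balanced fast path.** On balanced designs ($r$ replicates everywhere) the
interior REML solution coincides with the nested-ANOVA moment estimators
(`moment_estimates()`): $\hat\sigma^2 = MS_E$,
$\hat\omega^2 = (MS_{sp} - MS_E)/r$,
$\hat\tau^2 = (MS_{pair} - MS_{sp})/(2r)$, where $MS_{sp}$ is the
species-within-pair mean square adjusted for origin. When a moment estimate
is negative the solution lies on the boundary of the orthant; the fit then
evaluates the closed-form REML solutions of the candidate edge models
($\omega^2=0$, which is the Model 2 structure; $\tau^2=0$; both zero) and
keeps the candidate with the largest restricted likelihood. This closed
path makes the ~115,000 fits of the simulation study cheap and exactly
reproducible.

**General path.** Unbalanced designs (or `method = "optim"`) profile
$\sigma^2$ out of the restricted likelihood and optimize over log variance
ratios $(\log \tau^2/\sigma^2, \log \omega^2/\sigma^2)$ with Nelder–Mead
(iteration cap 200, relative tolerance $10^{-12}$), again comparing against
one-dimensional boundary candidates. A component is reported as on the
boundary when its estimate falls below $10^{-8}$ times the total variance.
The test suite verifies that the optimizer agrees with the closed form to
$10^{-6}$ on balanced data and with lme4 on unbalanced data.

Degenerate inputs: fully constant data return all-zero components with
every boundary flag set; Model 3 is refused when every species has a single
replicate ($\omega^2$ and $\sigma^2$ are then confounded). Model 1's
residual variance uses the unbiased $N-2$ divisor (the REML convention),
which makes its F-test the classical one-way ANOVA test.

## Small-sample inference

`kr_test()` implements the first-order Kenward–Roger (1997) adjustment: the
asymptotic GLS covariance of $(\hat\mu,\hat\beta)$ is inflated using the
asymptotic covariance of the variance-component estimates (inverse expected
REML information), and the Wald F for the one-degree-of-freedom origin
contrast is scaled with a moment-matched denominator df. Because the
covariance is linear in $(\tau^2,\omega^2,\sigma^2)$, the derivative
matrices are 0/1 block patterns assembled analytically and the
second-derivative term of the adjustment vanishes; no numerical
differentiation is involved. The later (2009) modified variant is
deliberately not used: the original method is exact on the balanced
variance-component designs this package targets, and the test suite checks
that on balanced interior fits the KR p-value reproduces the exact
balanced-ANOVA F-test (`exact_f_test()`, $F = MS_{origin}/MS_{sp}$ with
$p-1$ denominator df, identical to a paired t-test on species means) to
$10^{-8}$, and that off balance it matches pbkrtest to $10^{-5}$.

**Boundary policy.** When a variance component is estimated at zero, its
row and column are dropped from the adjustment (the limit of zero
information weight); the result is flagged and a warning raised. At a
boundary the exact-F identity no longer holds for any implementation — the
fitted covariance differs from the ANOVA one — so the tests assert validity
(p in [0,1], positive df) rather than exactness there. An independent
implementation that instead keeps a tiny positive component gives p-values
differing in the third decimal in the cases we examined.

For unbalanced or incomplete data `bootstrap_test()` offers a parametric
bootstrap alternative: refit under the null, simulate from the null fit
(iid normal effects), refit the alternative, and use the
$(1 + \#\{F^* \ge F\})/(B+1)$ convention so the p-value is never zero. The
F statistics compared are the KR-scaled statistics, resample failures are
excluded and reported, and $B \ge 99$ is enforced.

## The synthetic-data generator

`simulate_paired_data()` reproduces the generative process of the
simulation study:

1. **Yule tree.** One phylogeny per dataset, one tip per pair, grown from a
   single lineage: while $k$ lineages exist the next birth waits
   $\mathrm{Exp}(k\lambda)$ and a uniformly chosen lineage splits; the tree
   is observed at the instant the $p$-th lineage is born. The expected
   origin-to-present depth is therefore $\sum_{k=1}^{p-1} 1/k$ (verified by
   Monte Carlo against this closed form). Observing *at* the final birth
   means the youngest cherry has zero-length pendant edges — those two
   pairs are maximally related. The birth rate defaults to 1 and is
   unidentifiable downstream because of step 3, so it is not exposed as a
   meaningful tuning parameter.
2. **Brownian evolution.** Tip values accumulate independent normal
   increments with variance equal to branch length (root value 0, unit
   diffusion). Tip covariance equals shared root-to-tip path length. The
   stem below the root is skipped: a shared increment would shift all tips
   equally and is removed by the centering in step 3 anyway.
3. **Scaling.** Tip values are centered and rescaled so their *sample*
   variance (divisor $p-1$) equals $\tau^2$ exactly
   (`scale_pair_effects()`). This reads the generator's variance constraint
   as an exact empirical one; centering is harmless because $\mu$ absorbs
   location. A consequence worth knowing: the realized pair-effect variance
   is not random, which slightly sharpens variance-recovery comparisons at
   $\tau^2$.
4. Species effects iid $N(0,\omega^2)$ (one per species), errors iid
   $N(0,\sigma^2)$ (one per replicate), and the response assembled exactly
   as in the model equation; the latent draws are stored so reconstruction
   is exact to floating point.

With `phylogenetic = FALSE` the pair effects are instead iid
$N(0, \tau^2)$, matching the fitted model exactly; the test suite uses this
mode to check that empirical correlations converge to $\rho$ and $\theta$.

**What the generator does and does not emulate.** It reproduces correlated
pair effects of the kind shared ancestry creates, while the fitted model
assumes iid pairs — so passing Type I error checks demonstrate robustness
to this specific, tree-structured misspecification at the simulated design
sizes. It does not emulate extinction (birth–death trees),
non-Brownian trait evolution (e.g. Ornstein–Uhlenbeck), within-pair tree
structure (both species share one tip value), heteroscedastic residuals,
non-Gaussian traits, or missing data. Conclusions about real data carry the
same caveats.

**Seeding.** Every user-facing simulator accepts a `seed` and leaves the
global RNG untouched (`withr::with_seed`). The grid derives one substream
per dataset from the master seed, the condition's *values* and the dataset
index, so grids are reproducible, order-independent and parallelizable by
condition; all derived seeds stay below $2^{31}$.

## The simulation study

`run_grid()` crosses $\tau^2, \omega^2, \sigma^2 \in \{0.1, 0.2, 0.5, 1.0\}$
(64 conditions) at 30 pairs × 5 replicates, simulates datasets under the
null ($\beta = 0$) or alternative ($\beta = 0.5$), and records rejection
at $\alpha = 0.05$ (strict `p < alpha`) for Model 1 (classical ANOVA F),
and Models 2 and 3 (REML + KR). Fit failures count as non-rejections —
conservative for Type I error — and are reported per condition; none occur
at the study's design sizes.

`summarize_grid()` reports two kinds of maxima. The raw per-condition
maximum is the worst single grid cell. The *marginal* maximum first
averages the rejection rate at each level of one variance component over
the other two (the trend curves one would draw through the 64-point cloud)
and then takes the peak. The headline inflation figures of this literature
are read off such trend curves, and the package's acceptance checks use the
marginal maxima for that reason; both quantities are returned.

Replication sizes used by the packaged checks — 300 datasets per null
condition, 100 per power condition, and 1000 for parameter recovery — were
chosen as the smallest sizes whose Monte-Carlo standard errors are
comfortably below the decision margins (about 0.013 for a per-condition
rate at 300, 0.003–0.007 for marginal means); the full study runs in about
a minute per grid on one CPU. `run_grid(n_datasets = 1000)` reproduces the
original replication scale directly if wanted.

Observed behavior (recomputed by `scripts/acceptance.R` and the test
suite): Model 3 holds its aggregate Type I error at 0.05 across all 64
conditions; Model 2's marginal Type I error peaks around 40% (raw
per-condition peak near 49% at $\omega^2 = 1, \sigma^2 = 0.1$) and Model
1's around 25% (raw near 34%); inflation grows with species variance,
shrinks with residual variance, and — for Model 1 only — shrinks with pair
variance, while Model 2 is insensitive to $\tau^2$ because the pair effect
cancels from the within-pair contrast. Power declines as any variance
component grows.

## Design choices that were genuinely open

* **Origin coding.** Invasive = 1, so $\beta$ is the invasive-minus-native
  contrast from a single indicator.
* **One tree per dataset.** The generator grows a fresh Yule tree for every
  simulated dataset rather than reusing one per condition, avoiding
  conditioning a whole condition's replicates on a single topology; pass
  `tree =` to reuse one deliberately.
* **Tip-to-pair assignment** is by tip label order; pair labels are
  exchangeable, so this is a pure bookkeeping convention.
* **Two-sided testing.** The F-test of a single contrast is inherently
  two-sided; no one-sided variant is offered.
* **Taxonomic classification** of the packaged 19-pair table is rule-based:
  congeneric if the genus tokens match, within-order if listed in the
  within-order block, confamilial otherwise — no taxonomy database is
  consulted. Family membership is not modeled as an additional grouping
  layer (several families contribute multiple pairs), keeping the model at
  the two layers the design motivates.

## Known limitations

* No general formula interface: the fixed part is intercept + origin, the
  random part one of the three structures. This is the scope of the design,
  not an oversight.
* Exactly two species per pair; more general clusters need a different
  covariance structure.
* The KR boundary policy (dropping zero components) is one of several
  defensible conventions; p-values at boundary fits differ slightly between
  conventions.
* Balanced-design closed forms assume a common replicate count; mildly
  unbalanced data silently use the slower optimizer path, which is correct
  but not fast enough for very large grids.
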