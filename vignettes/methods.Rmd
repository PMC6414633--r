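---
title: "Methods: phylogenetic comparative analysis of cecal allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of cecal allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `cecaphylo`, the
reasoning for each numerical and design choice, what the synthetic-data
generator does and does not emulate, and the limitations we know about.

## 1. The model

For $n$ species with log10 cecal length $y$, log10 body mass $m$, and
categorical cofactors (diet, flight ability, higher clade), the package
fits

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}(0, \sigma^2 V), $$

where $X$ contains an intercept, $m$, and treatment-coded dummies for
whichever factors a design includes, and $V$ is a residual covariance
implied by a model of trait evolution on the phylogeny:

- **independent** — $V = I$; species are exchangeable and the fit is
  ordinary least squares. This is the "no phylogeny" baseline.
- **brownian** — $V = C$, where $C_{ij}$ is the shared path length from
  the root to the most recent common ancestor of tips $i$ and $j$
  (`phylo_vcv`, computed by `ape::vcv.phylo`). Under Brownian motion a
  trait's covariance between two species is proportional to their
  shared evolutionary history.
- **lambda** — off-diagonal entries of $C$ multiplied by $\lambda$,
  diagonal untouched. $\lambda = 0$ recovers independence with
  Brownian tip variances; $\lambda = 1$ recovers Brownian motion. The
  admissible maximum is $\max_i C_{ii} / \max_{i \ne j} C_{ij}$ — the
  largest value keeping the matrix a valid covariance — which can
  exceed 1 on non-ultrametric trees (`lambda_max`).
- **ou** — an Ornstein–Uhlenbeck (stabilizing-selection) correlation,
  $V_{ij} = \exp(-\alpha\, d_{ij})$ with unit diagonal, where
  $d_{ij} = C_{ii} + C_{jj} - 2 C_{ij}$ is the patristic distance.
  Correlation decays with distance at rate $\alpha$; $\alpha \to 0$
  approaches a fully correlated matrix and large $\alpha$ approaches
  independence. This is the stationary-OU form used by
  `nlme`'s `corMartins` structure, and our fits match that
  implementation to machine precision (verified in the test suite).

Given $V$, $\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$ via a
Cholesky whitening of $V$ (never an explicit inverse). Two scale
estimates are kept deliberately distinct:

- $\hat\sigma^2_{\mathrm{ML}} = \mathrm{RSS}_V / n$ enters the
  log-likelihood and AIC, so AICs are comparable across designs;
- $\hat\sigma^2_{\mathrm{resid}} = \mathrm{RSS}_V / (n - p)$ enters the
  coefficient standard errors, and t-tests use $n - p$ residual
  degrees of freedom. With 155 species and the clade + diet design
  (14 columns) this gives 141 df.

All likelihoods are ML, not REML: REML likelihoods are not comparable
across fixed-effect structures, and the ladder compares designs.

## 2. Branch lengths and tree variants

Composite phylogenies often lack meaningful branch lengths, so the
pipeline analyses each tree under explicit conventions:

- `pagel_branch_lengths` — every internal edge gets length 1 and each
  terminal edge is stretched so the tree is ultrametric (all tips
  equidistant from the root). This encodes "only topology is trusted"
  while keeping contemporaneous tips.
- `unity_branches` — every edge gets length 1 (tips not necessarily
  contemporaneous).
- `as-given` — the input lengths are used unchanged.

Pagel's $\lambda$ is reported per variant; the parsimony-based PTP test
is branch-length invariant, so only the topology matters there. The
regression ladder uses the first configured variant.

## 3. Phylogenetic signal

**Continuous characters.** `lambda_ml` profiles the mean and $\sigma^2$
analytically and maximizes the one-dimensional $\lambda$ likelihood
with `stats::optimize` (tolerance $10^{-8}$) on
$[0, \lambda_{\max}]$, comparing the interior optimum with both
endpoints. Significance is a likelihood-ratio test against
$\lambda = 0$ on one $\chi^2$ degree of freedom. Estimates match
`phytools::phylosig` (checked in the tests) and are recovered without
bias at both ends of the range in simulation.

**Categorical characters.** `fitch_length` computes the parsimony
length with the exact multifurcating generalization of the Fitch
algorithm: at each internal node the step count increases by the
number of children minus the largest number of children sharing any
one state. On binary nodes this is the classical Fitch rule; on
polytomies it remains exact, which we verified against exhaustive
enumeration of all internal-state assignments on thousands of random
binary and polytomous instances. `ptp_test` compares the observed
length with the lengths obtained under a null — either random
pure-birth (Yule) topologies of the same size (`yule_tree`, depth 10)
or shuffled tip states — and reports
$p = \#\{\text{null} \le \text{observed}\}/B$. When the count is zero
the reported value is $10/B$, a deliberately conservative bound (e.g.
$p = 0.001$ at $B = 9999$), so a Monte Carlo p-value is never reported
as exactly zero. Under the shuffle null the empirical type-I error
sits at its nominal 5% level (checked in the acceptance tests).

## 4. The model ladder

`study_designs()` defines nine designs: the simple allometry
($y \sim m$); three single-factor additive designs (clade, diet,
flight); clade + diet; clade + diet + flight; and three single-factor
designs in which the factor also interacts with the slope. Crossed
with the three weighting schemes (independent, Brownian, OU with
estimated $\alpha$) this is a 27-fit ladder. Fits are ranked by
unrounded AIC with $k$ = number of coefficients + 1 (for $\sigma^2$)
+ 1 if $\alpha$ is estimated — the same parameter counting as
`nlme::gls`, so AICs agree with that package exactly. Models with
$\Delta\mathrm{AIC} \ge 3$ from the best fit are flagged as rejected.
A design that cannot be fit (e.g. a rank-deficient interaction when a
factor level has too few species) is reported as a missing row, never
a hard failure of the ladder.

$\alpha$ is estimated by profiling: a 30-point log-spaced grid on
$[10^{-6}, 50 \cdot (10/\text{depth})]$ locates the basin and
`stats::optimize` (tolerance $10^{-6}$) refines it. On a depth-10 tree
the upper bound is 50, where $\exp(-\alpha d)$ is numerically zero for
any resolvable pair — effectively the OLS limit — so the search covers
the full identifiable range.

Factors are treatment-coded against explicit reference levels
(defaults: clade *Inopinaves*, diet *carnivore-vertebrates*, flight
*strong flyer*). Because treatment contrasts are only interpretable
against their reference, `relevel_fit` refits the best model under a
second reference set (*Galloanserae*, *herbivore*) and the pipeline
reports both blocks; the refit is the same model (identical
likelihood, AIC, and fitted values — asserted in the tests), only the
parameterization changes. The shared allometric slope is tested
against the isometric null of 1/3 (a linear dimension scaling with the
cube root of mass) with the same $n - p$ df t-test.

## 5. The synthetic-data generator

`make_study_like_dataset(synthetic_config(...))` builds a dataset with
the full statistical structure of the analysis, with known truth:

1. a Yule tree (`n_taxa = 155`, depth 10) from the package's own
   pure-birth generator;
2. log10 body mass by Brownian motion (root `mass_root = 2.7`, i.e.
   ~500 g, rate `mass_sigma2 = 0.06` — spanning roughly 10 g to
   100 kg, the realistic avian range);
3. seven clades carved as monophyletic blocks of the tree, and diet
   and flight states evolved by a symmetric Markov (Mk) process
   (`mk_rate = 0.02`, chosen so parsimony lengths land in the
   30–45-step range typical of a 155-species diet character); any
   factor level the Mk process failed to produce is re-seeded into
   random tips so every design stays estimable;
4. expected log cecal length
   `intercept + true_slope * log_mass + clade offset + diet offset`
   with `true_slope = 1/3` (isometry) and `intercept = -1.3243458`
   (so that a 500 g reference-level carnivore has a ~1 cm cecum);
   clade and diet offsets default to effect sizes of realistic
   magnitude (herbivore +0.459, insectivore +0.387, omnivore +0.319,
   Columbaves −1.236, Aequorlitornithes +0.446, ...);
5. residuals drawn from the OU model with `alpha = 0.17` and
   `sigma2 = 0.16` — intermediate phylogenetic signal on a depth-10
   tree;
6. back-transformation `cecal_length_cm = max(10^y - 0.1, 0)`, the
   inverse of the analysis transform `y = log10(cm + 0.1)`, which
   also produces a realistic fraction of exactly-zero (absent) ceca.

What it does **not** emulate: measurement error, within-species
variation, sample-size weighting, non-stationary or clade-specific
evolutionary rates, and correlation between diet and mass beyond what
the shared tree induces. It is a test harness for the estimators, not
a model of avian gut evolution.

## 6. Numerical and software choices

- Covariances are factored once per fit (Cholesky); singular or
  indefinite matrices yield a $-\infty$ likelihood rather than an
  error during optimization.
- Rank deficiency is detected by pivoted QR and reported with the
  names of the collinear columns.
- `transform_covariance` under the independent model returns
  $\mathrm{diag}(C)$ (Brownian tip variances without correlation);
  `gls_fit`'s independent model uses the identity matrix so that it is
  exactly OLS. On ultrametric trees these coincide up to scale; the
  distinction only matters off-ultrametric, where OLS is the intended
  baseline.
- Tree I/O, the Brownian covariance, and pruning are delegated to
  `ape`; multivariate normal draws to `MASS`. Everything
  methodological — Pagel branch lengths, the covariance transforms,
  $\lambda$ and $\alpha$ estimation, parsimony, PTP, the Yule and Mk
  generators, the GLS core — is implemented in the package and
  cross-checked in the tests against `nlme`, `phytools`, and exhaustive
  oracles.
- Every stochastic routine takes an explicit integer seed; replicate
  seeds inside permutation loops are derived as `seed + i` so results
  are reproducible and individual replicates re-runnable.

## 7. Known limitations

- **OU $\alpha$ is upward-biased in ML at this scale.** With 155 taxa,
  a depth-10 tree, and true $\alpha = 0.17$, the ML estimate averages
  ≈ 0.29 across replicates. This is a property of the likelihood, not
  of our optimizer — `nlme::gls` with `corMartins` returns identical
  estimates — and it shrinks with tree size.
- **$\alpha$ uncertainty is not propagated into coefficient standard
  errors.** SEs condition on the plugged-in correlation structure, as
  in standard GLS software. In simulation, nominal 95% intervals from
  fits with $\alpha$ re-estimated per replicate cover the deep clade
  contrasts only ~83–89% of the time, while intervals from fits at the
  generating $\alpha$ achieve 92–97% (the package's coverage test).
  Contrasts between deep clades are the quantities most sensitive to
  this; slopes and diet offsets are less affected.
- The $\Delta\mathrm{AIC} \ge 3$ rejection rule is a conventional
  screening threshold, not a calibrated test.
- The Yule-topology PTP null conditions only on the number of tips,
  not on the observed tree shape; the shuffle null conditions on the
  topology and is the stricter test of character–tree association.
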