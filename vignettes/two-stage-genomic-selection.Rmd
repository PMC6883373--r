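---
title: "Models and methods: two-stage testcross genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: two-stage testcross genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
mixed models for multi-environment testcross trials, the Bayesian G-BLUP and
reaction-norm prediction models, the cross-validation and selection rules,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The breeding design being modelled

A cohort of doubled-haploid (DH) maize lines is produced from bi-parental
crosses and genotyped with cheap dominant sequence-tag markers (presence or
absence of an amplified repeat tag, coded 0/1). Roughly half the lines are
crossed to a tester and evaluated for grain yield and agronomic traits in
replicated stage-I trials at several well-watered (WW) locations and one
managed water-stress (WS) location; the remaining lines are genotyped but
never phenotyped. Genomic prediction transfers information from the tested
to the untested half. Both cohorts are then culled — phenotyped lines on
their BLUEs, unphenotyped lines on their GEBVs — and the survivors meet in
common stage-II trials, crossed to shared testers, where their hybrids can
be compared head to head against commercial checks. The package simulates
this design, fits its models, and reproduces its selection and cost
arithmetic.

## Trial mixed models

For a trait measured on genotype $i$ at location $j$, replicate $r$, block
$k$:

$$Y_{ijrk} = \mu + L_j + R_{r(j)} + B_{k(rj)} + G_i + GL_{ij} + \varepsilon_{ijrk}$$

with location and replicate-within-location fixed, incomplete blocks
$B \sim N(0, \sigma^2_{B})$ and line-by-location interaction
$GL \sim N(0, \sigma^2_{GL})$ random, and
$\varepsilon \sim N(0, \sigma^2_e)$. The single-location (WS) model drops
the location terms; the across-trial model adds trial as a fixed effect,
with comparability across trials supplied by shared check entries (a
union-find connectivity check records whether the trial/entry graph is
connected).

Two fits serve two purposes, mirroring the convention of trial-analysis
software: genotype *fixed* for per-entry BLUEs and standard errors, and
genotype *random* for variance components, BLUPs, and the entry-mean
heritability over $l$ locations and $r$ replicates,

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GL}/l + \sigma^2_e/(lr)},$$

together with $\mathrm{CV} = 100\,\sqrt{\sigma^2_e}/\bar{y}$ and
$\mathrm{LSD}_\alpha = t_{1-\alpha/2,\nu}\sqrt{2\sigma^2_e/(lr)}$. A single
REML fit cannot deliver both BLUEs and $\sigma^2_G$, hence the two-fit
design. Estimation uses `lme4` REML with the `bobyqa` optimizer tightened
to `rhoend = 1e-10`; on balanced designs without blocking this matches the
closed-form ANOVA expected-mean-squares estimators to better than $10^{-6}$
relative (a property the test suite asserts). BLUEs are estimated marginal
means over equal location/replicate weights (`emmeans`); missing plots are
simply dropped — mixed models handle unbalancedness natively, and no
imputation is attempted. Residual degrees of freedom for the LSD use the
balanced value $(g-1)(lr-1)$.

Published heritability tables for designs of this type are not always
reproducible from their own printed variance components under the formula
above (the number of effective locations entering a pooled analysis is
rarely stated); the package therefore asserts the formula, never any
particular printed $h^2$.

## Genomic relationship matrix

`build_grm()` drops monomorphic markers, mean-imputes missing codes per
marker, centers and scales each column and returns $G = X_sX_s'/p$. Two
deliberate choices:

* **Scaling divisor $n$** (population standard deviation), which makes
  $\operatorname{mean}(\operatorname{diag}(G)) = 1$ an *exact* invariant
  rather than an asymptotic one — the tests rely on it.
* **Coding-agnosticism**: dominant 0/1 codes and dosage 0/1/2 codes give
  the same $G$ after standardization, so the dominant rAmpSeq-style tags
  need no special treatment.

Because DH duplicates and family structure make $G$ rank-deficient by
construction, eigenvalues in $(-10^{-8}, 0]$ receive a $10^{-8}$ jitter; a
smaller eigenvalue is reported as an error (a genuinely non-PSD input).

## Bayesian G-BLUP and the reaction-norm interaction

On line-by-environment means $y_{ij}$ (BLUEs from stage I), three nested
variants:

$$\text{G+e:}\quad y_j = \mu + g_j + e_j \qquad
  \text{E+G+e:}\quad y_{ij} = \mu + E_i + g_j + e_{ij}$$
$$\text{E+G+GE+e:}\quad y_{ij} = \mu + E_i + g_j + gE_{ij} + e_{ij}$$

with $g \sim N(0, G\sigma^2_g)$ — equivalently, i.i.d. marker effects
$b_m \sim N(0, \sigma^2_b)$ with $\sigma^2_g = p\,\sigma^2_b$ (the fit
reports $\sigma^2_b = \sigma^2_g/p$) — and the reaction-norm interaction
covariance $(Z_gGZ_g')\circ(Z_EZ_E')\,\sigma^2_{gE}$: within an environment
the interaction is $G$-correlated across lines; across environments it is
independent, so with disjoint observations the covariance is block-diagonal
per environment. The WS management is a single site and uses G+e — there is
no environment or interaction term to estimate from one environment.

**Sampler.** A Gibbs sampler with flat priors on $\mu$ and $E_i$ and
scaled-inverse-$\chi^2(\nu_0 = 5, S_0)$ priors on each variance component,
with $S_0$ set so each random term's prior mode takes an equal share of
half the phenotypic variance (the residual mode takes the other half) —
the default behaviour of the Bayesian ridge/G-BLUP software family.
Numerically, $G_{tt}$ (training block) is eigendecomposed once,
$g = U a$, and the coefficients $a$ are sampled in the eigenbasis: when
every training line is observed once per environment the conditional
posterior of $a$ is *diagonal* and one iteration costs a handful of
$n \times n$ matrix-vector products, which is what keeps 100-repeat
cross-validation tractable; with missing cells the sampler falls back to a
dense Cholesky update (intended for modest $n$). Chain defaults are 15,000
iterations, 5,000 burn-in, thinning 5; the seed is mandatory and the chain
is bit-reproducible given it.

Posterior means of $g$, $gE$ and the intercepts are accumulated as
**Rao-Blackwellized conditional means** (the draws still drive the chain),
which cuts their Monte Carlo variance substantially; variance components
are summarized from their retained draws. With variance components held
fixed, the posterior mean of $g$ equals the dense mixed-model-equations
solution — the test suite checks this to $10^{-3}$ on toy problems.

**Prediction of untested lines.** Because all genotyped lines share the
joint prior $N(0, G\sigma^2_g)$, the posterior mean for an unphenotyped
line is its conditional expectation given the training lines,
$G_{nt}G_{tt}^{-1}\hat g_t$ (computed through the same eigendecomposition);
a line unrelated to all training lines gets its prior mean 0, and a
duplicate of a training line gets that line's fitted value.
Environment-specific predictions add $E_i$ and, when fitted, the
within-environment interaction conditional mean.

## Cross-validation

`make_folds()` partitions *lines* (not plots) into $k$ near-equal folds —
a held-out line is unobserved in every environment, mimicking the
genotyped-but-untested cohort — and repeats the partition `n_repeats`
times. Within a repeat the five test-fold prediction vectors are
concatenated and a single Pearson correlation with the observed values is
computed per environment; the accuracy table reports mean ± sd *across
repeats* (not folds). Folds are drawn uniformly without stratification by
population. Per-fold seeds are derived deterministically from the plan
seed. Within-tester scenarios restrict CV to each tester's lines;
across-tester pooling first centers values on the per-tester mean so
tester main effects cannot masquerade as genomic accuracy. Default CV
chains are shorter (1,500/500) than single-fit chains: correlations of
posterior means stabilize far earlier than the variance components
themselves, and the package's tests pin the CV accuracy to an independent
kernel-ridge oracle (ridge at the maximum-likelihood variance ratio on the
same folds) within ±0.1.

## Selection and comparison rules

* **Stage-I advancement** is strictly-above-cohort-mean, applied to BLUEs
  for the phenotyped cohort and GEBVs for the predicted cohort. Strict
  inequality is an arbitrary but fixed convention; ties at exactly the
  mean have probability zero for continuous criteria.
* **Top-fraction counts** use round-half-up: $0.15 \times 526 = 78.9
  \rightarrow 79$ and $0.15 \times 516 = 77.4 \rightarrow 77$, matching
  the published counts for those cohort sizes. Ties break by stable entry
  order. Percent improvement cells are round-half-up of
  $100(\text{candidate}/\text{reference} - 1)$, with a $10^{-9}$ guard
  absorbing floating-point error on exact .5 boundaries.
* **Stage-II comparisons** operate on hybrid (line × tester) means;
  checks never enter cohort statistics. Missing line × tester crosses are
  tolerated throughout. `advancement_rates()` selects the top fraction of
  the pooled check-free hybrid set and reports integer percent shares per
  cohort, which sum to 100 ± 1 by rounding.

Published comparison tables of this kind often print percent cells
computed from unrounded internal means; only cells arithmetically
consistent with their printed inputs are asserted by the tests.

## Cost model

An activity costs `cost_per_entry × n_entries × reps_per_site ×
rows_per_site × n_sites` — deliberately plain spreadsheet arithmetic, with
rows/sites treated as an opaque multiplier. Strategy totals are sums over
ledger rows; the GS:PS ratio is rounded to two decimals. Integer inputs
give exact integer dollar totals.

## What the simulator emulates — and what it does not

Defaults reproduce the stage-I study conditions: 12 bi-parental DH
families of 34–240 lines (1,492 genotyped; 851 phenotyped, per-family
counts as published), 4,657 dominant markers on 10 chromosomes of 160 cM,
trials at 3 WW + 1 WS locations with 2 replicates in incomplete blocks,
and grain-yield variance components of the published magnitude (WW:
$\sigma^2_G = 0.19$, $\sigma^2_{GxE} = 0.18$, $\sigma^2_e = 1.41$ around
6.03 t/ha; WS: $\sigma^2_G = 0.17$, $\sigma^2_e = 0.33$ around 3.25 t/ha).
Where the study design left details unstated, the generator chooses once:

* **Meiosis**: Haldane (no interference) — crossover count
  Poisson($L$/100), uniform positions. Interference is irrelevant to the
  downstream statistics tested.
* **Architecture**: 100 additive QTL placed uniformly at random among
  marker positions, effects normal, then *rescaled so the realized genetic
  variance hits the target exactly* (not just in expectation) — this turns
  variance targets into testable equalities. The per-environment GxE
  deviation is likewise orthogonalized against the main genetic value and
  rescaled, so per-environment genetic variance is exactly
  $\sigma^2_G + \sigma^2_{GxE}$.
* **Parental haplotypes** are drawn from program-level tag frequencies
  $U(0.2, 0.8)$, so markers segregate 1:1 within a family where parents
  differ and family structure emerges across populations.
* **Checks** are extra fixed-genotype entries replicated in every trial
  with phenotypes but no marker data, like commercial checks.
* **Tester layout** is free configuration (`n_testers`, tester and
  line-by-tester variances): published per-tester hybrid counts for
  programs of this type are not always mutually consistent, so no single
  layout is hard-coded. Stage-II-style runs use 3 common testers.
* **WS genetic values** share the ranking of the WW values (rescaled to
  the WS variance); real WW/WS genetic correlations are below 1, so
  simulated WS predictions are optimistic in that respect.

The generator does not simulate sequencing reads, marker QC (a filtered
matrix is the input), epistasis or dominance at the QTL, selection over
recurrent cycles, or spatial field trend. Passing tests therefore show
that the estimators recover the generating model's parameters and
orderings — not that real trials satisfy that model.

## Problem sizes and runtime

The test suite works at deliberately reduced scales — toys of 8–60 lines
for exactness checks, 200–500 lines for recovery and oracle comparisons,
30 replicate trials of 300 entries for variance-component calibration, and
one full-scale run (1,492 lines × 4,657 markers, 851 training / 641
predicted, 4 environments, 5-fold × 10-repeat CV) that completes in a few
minutes on one CPU thanks to the eigenbasis sampler. The 100-repeat CV of
a production analysis uses the same code path and scales linearly in
repeats.

## Known limitations

* The dense-Cholesky fallback for incomplete line × environment tables is
  cubic per iteration and meant for hundreds, not thousands, of lines.
* BLUE standard errors from `emmeans` use asymptotic degrees of freedom.
* Tester effects in stage-II simulation are constant across environments
  within a management.
* The package models a single trait at a time; no multi-trait selection
  index is provided.
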