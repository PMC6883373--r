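# maizegs

Simulation and analysis toolkit for two-stage maize testcross breeding
programs that combine **phenotypic selection (PS)** and **genomic selection
(GS)**, written for quantitative geneticists and breeding-program analysts.

A typical program of this kind genotypes every doubled-haploid (DH) line it
produces, testcrosses and field-phenotypes only about half of them in
stage-I multi-location yield trials, predicts the untested half from the
tested half with G-BLUP, advances the best of both cohorts into common
stage-II trials, and asks two questions: do GS-advanced hybrids perform as
well as PS-advanced ones, and what does GS save? This package implements
every computational link of that chain:

* **`simulate_program()` / `simulate_trials()`** — synthetic DH breeding
  programs: bi-parental families with Haldane (no-interference) meiosis,
  dominant presence/absence sequence-tag markers, additive QTL rescaled to
  exact genetic-variance targets, and plot-level alpha-lattice trials under
  well-watered (WW) and managed water-stress (WS) conditions.
* **`fit_multi_location()` / `fit_single_location()` / `fit_across_trials()`**
  — the trial mixed models

  `Y_ijrk = mu + L_j + R_r(L_j) + B_k[R_r(L_j)] + G_i + GL_ij + e_ijrk`

  (location and replicate fixed, incomplete blocks and line-by-location
  random; REML) yielding BLUEs, variance components, and via
  `trait_summary()` the entry-mean heritability
  `h2 = s2_G / (s2_G + s2_GL/l + s2_e/(l r))`, LSD and CV%.
* **`build_grm()` / `fit_genomic()` / `predict_gebv()`** — the genomic
  relationship matrix `G = X_s X_s' / p` on the column-standardized marker
  matrix, and Gibbs-sampled Bayesian G-BLUP with line effects
  `g ~ N(0, G s2_g)`, optionally extended by the reaction-norm interaction
  `gE ~ N(0, (Z_g G Z_g') ∘ (Z_E Z_E') s2_gE)`. Unphenotyped lines are
  predicted through the joint genomic prior.
* **`make_folds()` / `run_cv()` / `tester_scenarios()`** — repeated random
  five-fold cross-validation at the line level (a held-out line is unseen in
  every environment), reporting Pearson accuracy as mean ± sd across
  repeats, within and across testers.
* **`select_above_average()` / `top_fraction()` / `comparison_table()` /
  `advancement_rates()`** — the advancement rules (strictly-above-mean BLUE
  or GEBV; round-half-up top-fraction counts) and stage-II cohort-vs-check
  comparison tables with integer percent yield improvements.
* **`activity_cost()` / `strategy_cost()` / `cost_ratio()`** — spreadsheet-
  faithful activity-based cost accounting of PS versus GS.

`run_pipeline()` ties all stages together from a single seeded
configuration.

## Worked example

```r
library(maizegs)

# a small two-population program: 60 genotyped lines, 40 of them phenotyped
cfg <- sim_config(n_populations = 2, lines_per_population = c(30, 30),
                  phenotyped_per_population = c(20, 20),
                  n_chromosomes = 2, markers_per_chromosome = 50,
                  n_qtl = 20, blocks_per_rep = 4, n_checks = 2, seed = 7)
program <- simulate_program(cfg)
pheno   <- simulate_trials(program)
blues   <- stage_blues(pheno, "GY")         # per-environment entry BLUEs
grm     <- build_grm(program$genotypes)
grm
#> GRM over 60 lines from 78 polymorphic markers; mean diag = 1.000000

ww  <- blues[blues$management == "WW", c("line", "env", "value")]
fit <- fit_genomic(ww, grm, iters = 2000, burnin = 500, thin = 2, seed = 11)
fit
#> Genomic fit [E+G+e]: 40 training lines, 3 environment(s)
#>   posterior means: sigma2_g = 0.7863, sigma2_gE = 0.0000, sigma2_e = 0.9954

holdout <- program$lines$line[!program$lines$phenotyped]
gebv <- predict_gebv(fit, holdout)
head(gebv, 3)
#>       line       gebv
#> 1 P01_L021 1.03510043
#> 2 P01_L022 0.20631388
#> 3 P01_L023 0.06254591
```

The GEBVs are the posterior means of the genomic values of the 20 lines
that were never phenotyped, predicted through their marker relationships to
the 40 tested lines; lines with positive GEBV above the cohort mean would
advance to stage II under the GS rule. The cost ledger bundled with the
package evaluates the program's budget:

```r
cost_report(read_cost_ledger(system.file("extdata", "stage1_cost_ledger.csv",
                                         package = "maizegs")))
#> $ps_total
#> [1] 134280
#> $gs_total
#> [1] 91870
#> $ratio
#> [1] 0.68
```

i.e. genotyping every line but field-testing only the training half costs
68% of phenotyping everything.

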