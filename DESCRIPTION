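Package: maizegs
Title: Two-Stage Testcross Genomic Selection for Maize Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a two-stage maize testcross
    breeding program that combines phenotypic and genomic selection. Simulates
    doubled-haploid (DH) populations with dominant presence/absence markers and
    multi-environment alpha-lattice testcross trials; fits the program's
    multi-location, single-location and across-trial mixed models to obtain
    BLUEs, variance components, entry-mean heritability, LSD and CV; builds the
    genomic relationship matrix and fits G-BLUP and marker-by-environment
    reaction-norm models by Gibbs sampling to predict untested lines; runs
    repeated five-fold cross-validation of prediction accuracy within and
    across testers; applies above-average and top-fraction advancement rules
    with cohort comparison tables and advancement-rate shares; and reproduces
    the program's activity-based cost accounting for phenotypic versus genomic
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
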