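# Synthetic doubled-haploid (DH) breeding-program generator.
#
# Emulates a stage-I testcross evaluation: 12 bi-parental DH populations
# (34-240 lines each, 1492 lines in total) genotyped with ~4657 dominant
# presence/absence sequence-tag markers, testcrossed and evaluated in
# alpha-lattice trials with two replicates under well-watered (WW) and
# managed water-stress (WS) conditions. Every stochastic quantity is drawn
# under a caller-supplied seed; identical seeds give identical output.

#' Build an evenly spaced genetic map
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_cM Map length per chromosome in centimorgans; recycled
#'   to `n_chromosomes`.
#' @param markers_per_chromosome Marker count per chromosome; recycled.
#' @return Data frame with columns `marker`, `chrom`, `pos_cM`; positions are
#'   strictly increasing within a chromosome.
#' @export
make_genetic_map <- function(n_chromosomes = 10,
                             chrom_length_cM = 160,
                             markers_per_chromosome = 466) {
  if (n_chromosomes < 1) stop_("n_chromosomes must be >= 1")
  len <- rep_len(chrom_length_cM, n_chromosomes)
  m <- rep_len(markers_per_chromosome, n_chromosomes)
  if (any(len <= 0)) stop_("chromosome lengths must be > 0")
  if (any(m < 1)) stop_("markers_per_chromosome must be >= 1")
  chrom <- rep(seq_len(n_chromosomes), m)
  pos <- unlist(lapply(seq_len(n_chromosomes), function(cc) {
    if (m[cc] == 1) len[cc] / 2 else seq(0, len[cc], length.out = m[cc])
  }), use.names = FALSE)
  data.frame(marker = sprintf("M%05d", seq_along(chrom)),
             chrom = chrom, pos_cM = pos, stringsAsFactors = FALSE)
}

check_map <- function(map) {
  need <- c("marker", "chrom", "pos_cM")
  if (!all(need %in% names(map))) stop_("map must have columns marker, chrom, pos_cM")
  bad <- vapply(split(map$pos_cM, map$chrom),
                function(p) any(diff(p) < 0), logical(1))
  if (any(bad)) stop_("map positions must be non-decreasing within chromosomes")
  invisible(map)
}

# Parental origin (0 = parent A, 1 = parent B) of one DH gamete per marker,
# with crossovers placed under the Haldane (no-interference) model: the
# crossover count on a chromosome of length L cM is Poisson(L/100) and
# crossover positions are uniform.
dh_gamete_origins <- function(n_lines, map) {
  chroms <- split(seq_len(nrow(map)), map$chrom)
  out <- matrix(0L, n_lines, nrow(map))
  for (idx in chroms) {
    pos <- map$pos_cM[idx]
    L <- max(pos)
    for (i in seq_len(n_lines)) {
      n_co <- stats::rpois(1L, L / 100)
      start <- stats::rbinom(1L, 1L, 0.5)
      if (n_co == 0L) {
        out[i, idx] <- start
      } else {
        xo <- sort(stats::runif(n_co, 0, L))
        out[i, idx] <- (start + findInterval(pos, xo)) %% 2L
      }
    }
  }
  out
}

#' Simulate a bi-parental DH population
#'
#' Each DH line is a single recombinant gamete of the F1 doubled to complete
#' homozygosity, so its dominant marker code equals the tag code of the
#' inherited parental allele.
#'
#' @param parent_a,parent_b Integer vectors of 0/1 tag codes, one per map
#'   marker. The parents must differ at at least one marker.
#' @param n_lines Number of DH lines to generate (>= 1).
#' @param map Genetic map from [make_genetic_map()].
#' @param seed RNG seed.
#' @param coding `"01"` (default, dominant presence/absence) or `"012"`
#'   (diploid dosage; DH lines are homozygous so codes are 0/2).
#' @return Integer matrix of marker codes, lines in rows, markers in columns.
#' @export
simulate_dh_population <- function(parent_a, parent_b, n_lines, map,
                                   seed, coding = c("01", "012")) {
  coding <- match.arg(coding)
  check_map(map)
  p <- nrow(map)
  if (length(parent_a) != p || length(parent_b) != p)
    stop_("parent haplotypes must have one code per map marker (%d)", p)
  if (!all(parent_a %in% 0:1) || !all(parent_b %in% 0:1))
    stop_("parent haplotype codes must be 0/1")
  if (all(parent_a == parent_b)) stop_("monomorphic cross: parents are identical")
  if (!is.numeric(n_lines) || n_lines < 1) stop_("n_lines must be >= 1")
  with_seed(seed, {
    origin <- dh_gamete_origins(as.integer(n_lines), map)
    geno <- t(ifelse(t(origin) == 0L, parent_a, parent_b))
  })
  storage.mode(geno) <- "integer"
  if (coding == "012") geno <- geno * 2L
  colnames(geno) <- map$marker
  rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
  geno
}

#' Configuration of a synthetic two-stage breeding program
#'
#' Defaults reproduce the stage-I study conditions: 12 bi-parental DH
#' populations of 34-240 lines (1492 genotyped in total, 851 of them
#' testcrossed and phenotyped), 4657 dominant markers on 10 chromosomes,
#' trials in 3 WW locations plus 1 WS location with 2 replicates in
#' incomplete blocks, and grain-yield variance components of the magnitude
#' estimated in the program (WW: sigma2_G 0.19, sigma2_GxE 0.18, sigma2_e
#' 1.41 around a 6.03 t/ha mean; WS: sigma2_G 0.17, sigma2_e 0.33 around
#' 3.25 t/ha).
#'
#' @param n_populations Number of bi-parental populations.
#' @param lines_per_population Integer vector of DH family sizes.
#' @param phenotyped_per_population Lines per family entering stage-I trials
#'   (the rest form the genotyped-only prediction set).
#' @param n_chromosomes,chrom_length_cM,markers_per_chromosome Map layout.
#' @param n_qtl Number of additive QTL (placed at random marker positions).
#' @param environments Data frame with columns `label` and `management`
#'   (`"WW"` or `"WS"`).
#' @param n_reps Replicates per environment.
#' @param blocks_per_rep Incomplete blocks per replicate.
#' @param n_trials Number of connected trials the entries are split into.
#' @param n_checks Commercial checks replicated in every trial (phenotyped
#'   but never genotyped).
#' @param n_testers Common testers each line is crossed to.
#' @param variance_targets Named list per management with elements `G`,
#'   `GxE`, `e` (trait units squared). The WS management is modelled as a
#'   single environment, so its `GxE` must be 0.
#' @param trait_means Named numeric, trait mean per management.
#' @param sigma2_block,sigma2_rep,sigma2_loc Nuisance design variances.
#' @param sigma2_tester,sigma2_gxt Tester main-effect and line-by-tester
#'   variances (only used when `n_testers > 1`).
#' @param trait Trait column name.
#' @param seed RNG seed (mandatory).
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 12,
                       lines_per_population = c(34, 181, 185, 240, 162, 134,
                                                180, 110, 40, 51, 75, 100),
                       phenotyped_per_population = c(34, 91, 93, 126, 81, 67,
                                                     86, 55, 40, 51, 75, 52),
                       n_chromosomes = 10,
                       chrom_length_cM = 160,
                       markers_per_chromosome = c(rep(466, 7), rep(465, 3)),
                       n_qtl = 100,
                       environments = data.frame(
                         label = c("WW1", "WW2", "WW3", "WS1"),
                         management = c("WW", "WW", "WW", "WS"),
                         stringsAsFactors = FALSE),
                       n_reps = 2,
                       blocks_per_rep = 10,
                       n_trials = 1,
                       n_checks = 4,
                       n_testers = 1,
                       variance_targets = list(
                         WW = c(G = 0.19, GxE = 0.18, e = 1.41),
                         WS = c(G = 0.17, GxE = 0, e = 0.33)),
                       trait_means = c(WW = 6.03, WS = 3.25),
                       sigma2_block = 0.10,
                       sigma2_rep = 0.05,
                       sigma2_loc = 0.42,
                       sigma2_tester = 0,
                       sigma2_gxt = 0,
                       trait = "GY",
                       seed = NULL) {
  if (is.null(seed)) stop_("sim_config requires an explicit seed")
  cfg <- list(n_populations = as.integer(n_populations),
              lines_per_population = as.integer(lines_per_population),
              phenotyped_per_population = as.integer(phenotyped_per_population),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_cM = chrom_length_cM,
              markers_per_chromosome = markers_per_chromosome,
              n_qtl = as.integer(n_qtl),
              environments = environments,
              n_reps = as.integer(n_reps),
              blocks_per_rep = as.integer(blocks_per_rep),
              n_trials = as.integer(n_trials),
              n_checks = as.integer(n_checks),
              n_testers = as.integer(n_testers),
              variance_targets = variance_targets,
              trait_means = trait_means,
              sigma2_block = sigma2_block, sigma2_rep = sigma2_rep,
              sigma2_loc = sigma2_loc, sigma2_tester = sigma2_tester,
              sigma2_gxt = sigma2_gxt,
              trait = trait, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_populations < 1) stop_("n_populations must be >= 1")
    if (length(lines_per_population) != n_populations)
      stop_("lines_per_population must have length n_populations")
    if (length(phenotyped_per_population) != n_populations)
      stop_("phenotyped_per_population must have length n_populations")
    if (any(lines_per_population < 1)) stop_("family sizes must be >= 1")
    if (any(phenotyped_per_population > lines_per_population))
      stop_("cannot phenotype more lines than a family contains")
    if (any(chrom_length_cM <= 0)) stop_("chrom_length_cM must be > 0")
    if (n_qtl < 1) stop_("n_qtl must be >= 1")
    if (!all(c("label", "management") %in% names(environments)))
      stop_("environments needs columns label, management")
    if (!all(environments$management %in% c("WW", "WS")))
      stop_("management must be WW or WS")
    if (n_reps < 1 || blocks_per_rep < 1 || n_trials < 1 || n_testers < 1)
      stop_("counts must be >= 1")
    for (mg in unique(environments$management)) {
      vt <- variance_targets[[mg]]
      if (is.null(vt) || !all(c("G", "GxE", "e") %in% names(vt)))
        stop_("variance_targets$%s needs elements G, GxE, e", mg)
      if (any(vt < 0)) stop_("variance targets must be >= 0")
      if (is.na(trait_means[mg])) stop_("trait_means has no entry for %s", mg)
    }
    if (sum(environments$management == "WS") <= 1 &&
        "WS" %in% names(variance_targets) &&
        variance_targets$WS["GxE"] > 0)
      stop_("WS is a single environment: its GxE target must be 0")
    if (any(c(sigma2_block, sigma2_rep, sigma2_loc,
              sigma2_tester, sigma2_gxt) < 0))
      stop_("design variances must be >= 0")
  })
  invisible(cfg)
}

#' Default stage-I-scale simulation configuration
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed, ...) sim_config(seed = seed, ...)

# Exact centering/scaling of a draw to a target variance (divisor n-1).
scale_to_var <- function(x, target) {
  x <- x - mean(x)
  v <- stats::var(x)
  if (target == 0) return(rep(0, length(x)))
  if (v <= 0) stop_("cannot rescale a constant vector to positive variance")
  x * sqrt(target / v)
}

#' Simulate a genotyped DH breeding program with ground truth
#'
#' Draws parental tag haplotypes per population from program-level tag
#' frequencies, generates DH families by Haldane meiosis, places additive QTL
#' at random marker positions, and rescales genetic values exactly to the
#' configured genetic variance per management. Well-watered environments add
#' a line-by-environment deviation rescaled to the configured GxE variance;
#' the WS management is generated from the single-environment model with no
#' GxE term.
#'
#' @param config A [sim_config()].
#' @return Object of class `dh_program`: list with `genotypes` (lines x
#'   markers 0/1 matrix, checks excluded), `map`, `lines` (data frame of
#'   line, population, phenotyped flag, cohort), `truth` (long data frame
#'   line, env, management, g_true for lines and checks), `qtl`, `config`.
#' @export
simulate_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  map <- make_genetic_map(cfg$n_chromosomes, cfg$chrom_length_cM,
                          cfg$markers_per_chromosome)
  p <- nrow(map)
  with_seed(cfg$seed, {
    tag_freq <- stats::runif(p, 0.2, 0.8)
    geno_list <- vector("list", cfg$n_populations)
    line_tab <- vector("list", cfg$n_populations)
    for (k in seq_len(cfg$n_populations)) {
      repeat {
        pa <- stats::rbinom(p, 1L, tag_freq)
        pb <- stats::rbinom(p, 1L, tag_freq)
        if (any(pa != pb)) break
      }
      n_k <- cfg$lines_per_population[k]
      origin <- dh_gamete_origins(n_k, map)
      g <- t(ifelse(t(origin) == 0L, pa, pb))
      storage.mode(g) <- "integer"
      ids <- sprintf("P%02d_L%03d", k, seq_len(n_k))
      rownames(g) <- ids
      geno_list[[k]] <- g
      phen <- seq_len(n_k) <= cfg$phenotyped_per_population[k]
      line_tab[[k]] <- data.frame(line = ids, population = k,
                                  phenotyped = phen,
                                  cohort = ifelse(phen, "PS", "GS"),
                                  stringsAsFactors = FALSE)
    }
    X <- do.call(rbind, geno_list)
    colnames(X) <- map$marker
    lines <- do.call(rbind, line_tab)
    n <- nrow(X)

    qtl_idx <- sample.int(p, cfg$n_qtl)
    qtl_eff <- stats::rnorm(cfg$n_qtl)
    g_raw <- drop(X[, qtl_idx, drop = FALSE] %*% qtl_eff)

    envs <- cfg$environments
    mg_of <- stats::setNames(envs$management, envs$label)
    g_mgmt <- lapply(unique(envs$management), function(mg)
      scale_to_var(g_raw, cfg$variance_targets[[mg]]["G"]))
    names(g_mgmt) <- unique(envs$management)

    truth <- do.call(rbind, lapply(seq_len(nrow(envs)), function(e) {
      mg <- envs$management[e]
      ge_var <- cfg$variance_targets[[mg]]["GxE"]
      n_mg_env <- sum(envs$management == mg)
      dev <- if (ge_var > 0 && n_mg_env > 1) {
        # orthogonalized against the main genetic value, so per-environment
        # genetic variance is exactly sigma2_G + sigma2_GxE
        z <- stats::rnorm(n)
        z <- z - g_mgmt[[mg]] * stats::cov(z, g_mgmt[[mg]]) /
          max(stats::var(g_mgmt[[mg]]), 1e-12)
        scale_to_var(z, ge_var)
      } else rep(0, n)
      data.frame(line = lines$line, env = envs$label[e], management = mg,
                 g_true = g_mgmt[[mg]] + dev, stringsAsFactors = FALSE)
    }))

    # Checks: fixed phenotyped genotypes with no marker data. Their genetic
    # values are drawn once per management at the genetic variance of that
    # management, constant over environments.
    if (cfg$n_checks > 0) {
      chk <- sprintf("CHK%d", seq_len(cfg$n_checks))
      chk_val <- lapply(names(g_mgmt), function(mg)
        stats::rnorm(cfg$n_checks, 0, sqrt(cfg$variance_targets[[mg]]["G"])))
      names(chk_val) <- names(g_mgmt)
      truth_chk <- do.call(rbind, lapply(seq_len(nrow(envs)), function(e) {
        mg <- envs$management[e]
        data.frame(line = chk, env = envs$label[e], management = mg,
                   g_true = chk_val[[mg]], stringsAsFactors = FALSE)
      }))
      truth <- rbind(truth, truth_chk)
    }
    qtl <- data.frame(marker = map$marker[qtl_idx], effect = qtl_eff,
                      stringsAsFactors = FALSE)
  })
  structure(list(genotypes = X, map = map, lines = lines, truth = truth,
                 qtl = qtl, config = cfg),
            class = "dh_program")
}

#' @export
print.dh_program <- function(x, ...) {
  cat(sprintf("DH program: %d lines x %d markers in %d populations (%d phenotyped)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              x$config$n_populations, sum(x$lines$phenotyped)))
  invisible(x)
}

#' Simulate multi-environment testcross trials
#'
#' Generates plot-level records for the phenotyped lines and checks of a
#' simulated program. Plot value = management trait mean + location effect +
#' replicate-within-location effect + block effect + true genetic value (with
#' its environment deviation) + tester terms + residual, each drawn from
#' centered normal distributions at the configured variances. Blocks are
#' nested in replicates nested in locations (alpha-lattice layout); entries
#' are re-randomized to blocks in every replicate. Checks are replicated in
#' every trial.
#'
#' @param program A `dh_program` from [simulate_program()].
#' @param config Optionally a different [sim_config()] (defaults to the
#'   program's own).
#' @param entries Line IDs to lay out (default: the program's phenotyped
#'   lines).
#' @param seed RNG seed for the trial noise (default `config$seed + 1`).
#' @return Plot-level data frame (a PhenoTable) with columns `trial`,
#'   `location`, `management`, `rep`, `block`, `entry`, `line`, `tester`,
#'   `cohort` and one trait column.
#' @export
simulate_trials <- function(program, config = program$config,
                            entries = NULL, seed = config$seed + 1L) {
  stopifnot(inherits(program, "dh_program"))
  validate_sim_config(config)
  cfg <- config
  if (is.null(entries)) entries <- program$lines$line[program$lines$phenotyped]
  if (!all(entries %in% program$lines$line)) stop_("unknown entry IDs")
  cohort_of <- stats::setNames(program$lines$cohort, program$lines$line)
  chk <- unique(program$truth$line[!program$truth$line %in% program$lines$line])
  envs <- cfg$environments
  truth_key <- stats::setNames(program$truth$g_true,
                               paste(program$truth$line, program$truth$env))
  testers <- sprintf("T%d", seq_len(cfg$n_testers))

  with_seed(seed, {
    tester_eff <- stats::setNames(
      if (cfg$n_testers > 1) stats::rnorm(cfg$n_testers, 0, sqrt(cfg$sigma2_tester))
      else rep(0, cfg$n_testers), testers)
    all_units <- c(entries, chk)
    gxt <- matrix(if (cfg$n_testers > 1 && cfg$sigma2_gxt > 0)
      stats::rnorm(length(all_units) * cfg$n_testers, 0, sqrt(cfg$sigma2_gxt))
      else 0, length(all_units), cfg$n_testers,
      dimnames = list(all_units, testers))
    loc_eff <- stats::setNames(stats::rnorm(nrow(envs), 0, sqrt(cfg$sigma2_loc)),
                               envs$label)

    # line x tester hybrid units, split into trials; checks in every trial
    units <- expand.grid(line = entries, tester = testers,
                         stringsAsFactors = FALSE)
    units$trial <- sprintf("T%02d", (seq_len(nrow(units)) - 1L) %% cfg$n_trials + 1L)
    if (length(chk)) {
      chk_units <- expand.grid(line = chk, tester = testers[1],
                               trial = sprintf("T%02d", seq_len(cfg$n_trials)),
                               stringsAsFactors = FALSE)
      units <- rbind(units, chk_units[, names(units)])
    }
    units$entry <- if (cfg$n_testers > 1)
      ifelse(units$line %in% chk, units$line,
             paste(units$line, units$tester, sep = "/"))
    else units$line

    recs <- vector("list", nrow(envs) * cfg$n_reps * cfg$n_trials)
    ri <- 0L
    for (e in seq_len(nrow(envs))) {
      mg <- envs$management[e]
      lab <- envs$label[e]
      s2e <- cfg$variance_targets[[mg]]["e"]
      for (tr in unique(units$trial)) {
        u <- units[units$trial == tr, , drop = FALSE]
        n_u <- nrow(u)
        for (r in seq_len(cfg$n_reps)) {
          ord <- sample.int(n_u)
          per_block <- ceiling(n_u / cfg$blocks_per_rep)
          block <- (seq_len(n_u) - 1L) %/% per_block + 1L
          rep_eff <- stats::rnorm(1, 0, sqrt(cfg$sigma2_rep))
          blk_eff <- stats::rnorm(max(block), 0, sqrt(cfg$sigma2_block))
          uu <- u[ord, , drop = FALSE]
          gval <- truth_key[paste(uu$line, lab)]
          y <- cfg$trait_means[mg] + loc_eff[lab] + rep_eff + blk_eff[block] +
            gval + tester_eff[uu$tester] +
            gxt[cbind(uu$line, uu$tester)] +
            stats::rnorm(n_u, 0, sqrt(s2e))
          ri <- ri + 1L
          recs[[ri]] <- data.frame(
            trial = tr, location = lab, management = mg, rep = r,
            block = block, entry = uu$entry, line = uu$line,
            tester = uu$tester,
            cohort = ifelse(uu$line %in% chk, "check", cohort_of[uu$line]),
            y = unname(y), stringsAsFactors = FALSE)
        }
      }
    }
    pheno <- do.call(rbind, recs[seq_len(ri)])
  })
  names(pheno)[names(pheno) == "y"] <- cfg$trait
  rownames(pheno) <- NULL
  pheno
}
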