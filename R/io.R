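# CSV readers/writers for the pipeline's tables and the end-to-end driver.
#
# One flat CSV dialect throughout: comma-separated, UTF-8, "." decimal,
# "NA" for missing.

#' Read a genotype matrix CSV
#'
#' Expected layout: header row of marker IDs, first column of line IDs,
#' cells in \{0, 1, 2, NA\}.
#'
#' @param path CSV path.
#' @return Integer matrix, lines in rows.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_("genotype file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_("genotype file needs a line-ID column plus markers")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop_("duplicate line IDs in genotype file")
  X <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(X))) stop_("duplicate marker IDs in genotype file")
  suppressWarnings(storage.mode(X) <- "double")
  bad <- which(!(is.na(X) | X %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop_("invalid genotype code at line %s, marker %s",
          ids[bad[1, 1]], colnames(X)[bad[1, 2]])
  storage.mode(X) <- "integer"
  rownames(X) <- ids
  X
}

#' Write a genotype matrix CSV
#' @param X Genotype matrix (lines x markers).
#' @param path Output path.
#' @export
write_genotypes <- function(X, path) {
  df <- data.frame(line = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot-level phenotype table CSV
#'
#' Required columns: `trial`, `location`, `management`, `rep`, `block`,
#' `entry`, `tester`, `cohort`, plus at least one numeric trait column.
#' `management` must be `"WW"` or `"WS"`.
#'
#' @param path CSV path.
#' @return Data frame with an attribute `traits` naming the detected trait
#'   columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_("phenotype file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "location", "management", "rep", "block", "entry",
            "tester", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("phenotype file is missing column(s): %s", paste(miss, collapse = ", "))
  bad_mg <- setdiff(unique(df$management), c("WW", "WS"))
  if (length(bad_mg))
    stop_("unknown management label(s): %s", paste(bad_mg, collapse = ", "))
  traits <- names(df)[vapply(df, is.numeric, logical(1))]
  traits <- setdiff(traits, c("rep", "block"))
  if (!length(traits)) stop_("no numeric trait columns found")
  attr(df, "traits") <- traits
  df
}

#' Write a plot-level phenotype table CSV
#' @param pheno Phenotype data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration JSON
#'
#' @param path JSON file with a mandatory `seed` and optional elements
#'   `sim` (overrides for [sim_config()]), `chain`
#'   (`iters`/`burnin`/`thin`), `cv` (`k`/`n_repeats`), `selection_fraction`,
#'   and `cost_ledger` (CSV path).
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop_("pipeline config must supply a seed")
  cfg
}

#' Run the two-stage selection pipeline end to end
#'
#' Stage I: simulate the genotyped program and its testcross trials, compute
#' per-environment entry BLUEs, build the GRM, fit the genomic model on the
#' phenotyped (training) lines, predict the genotyped-only holdout, and
#' advance both cohorts by the above-average rule (BLUEs for the phenotyped
#' cohort, GEBVs for the predicted cohort). Stage II: simulate trials of the
#' advanced lines crossed to common testers, build the cohort comparison
#' table and advancement-rate shares, and evaluate the cost ledger.
#'
#' @param config Named list (or path to a JSON file readable by
#'   [read_pipeline_config()]). Elements: `seed` (mandatory); `sim` —
#'   overrides passed to [sim_config()]; `chain` — `iters`, `burnin`, `thin`
#'   for the stage-I genomic fit; `cv` — `k`, `n_repeats`, and chain
#'   settings for cross-validation (`n_repeats = 0` skips CV);
#'   `selection_fraction` (default 0.15); `stage2` — `n_testers`,
#'   `environments` overrides for the stage-II trials (`run = FALSE` skips
#'   stage II); `cost_ledger` — path to a cost CSV (default: the bundled
#'   stage-I ledger).
#' @param out_dir Optional directory; when given, the main tables are also
#'   written there as CSVs.
#' @return List with `program`, `blues`, `grm` (omitted from output tables),
#'   `genomic_fit_ww`, `genomic_fit_ws`, `gebv`, `selection`, `cv`,
#'   `stage2`, `comparison`, `advancement`, `costs`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$seed)) stop_("pipeline config must supply a seed")
  seed <- as.integer(config$seed)
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  chain <- utils::modifyList(list(iters = 15000L, burnin = 5000L, thin = 5L),
                             config$chain %||% list())
  cv_cfg <- utils::modifyList(list(k = 5L, n_repeats = 0L, iters = 1500L,
                                   burnin = 500L, thin = 2L),
                              config$cv %||% list())
  f_sel <- config$selection_fraction %||% 0.15

  ## ---- stage I ----
  program <- simulate_program(cfg)
  pheno <- simulate_trials(program)
  blues <- stage_blues(pheno, trait = cfg$trait)
  grm <- build_grm(program$genotypes)

  train <- program$lines$line[program$lines$phenotyped]
  holdout <- program$lines$line[!program$lines$phenotyped]
  ww_blues <- blues[blues$management == "WW", c("line", "env", "value")]
  ws_blues <- blues[blues$management == "WS", c("line", "env", "value")]

  fit_ww <- if (nrow(ww_blues))
    fit_genomic(ww_blues, grm, variant = "auto", iters = chain$iters,
                burnin = chain$burnin, thin = chain$thin, seed = seed + 1L)
  fit_ws <- if (nrow(ws_blues))
    fit_genomic(ws_blues, grm, variant = "G+e", iters = chain$iters,
                burnin = chain$burnin, thin = chain$thin, seed = seed + 2L)

  gebv <- if (!is.null(fit_ww) && length(holdout))
    predict_gebv(fit_ww, holdout) else NULL

  # PS cohort: above-average across-WW BLUE; GS cohort: above-average GEBV
  ps_crit <- tapply(ww_blues$value, ww_blues$line, mean)
  ps_sel <- select_above_average(ps_crit, "above-average BLUE")
  gs_sel <- if (!is.null(gebv))
    select_above_average(stats::setNames(gebv$gebv, gebv$line),
                         "above-average GEBV")
  advanced <- c(ps_sel$entry[ps_sel$selected],
                if (!is.null(gs_sel)) gs_sel$entry[gs_sel$selected])

  cv_res <- NULL
  if (cv_cfg$n_repeats > 0) {
    plan <- make_folds(train, k = cv_cfg$k, n_repeats = cv_cfg$n_repeats,
                       seed = seed + 3L)
    cv_res <- run_cv(ww_blues, grm, plan, iters = cv_cfg$iters,
                     burnin = cv_cfg$burnin, thin = cv_cfg$thin)
  }

  ## ---- stage II ----
  stage2_cfg <- config$stage2 %||% list()
  run_s2 <- stage2_cfg$run %||% TRUE
  stage2 <- comparison <- advancement <- NULL
  if (isTRUE(run_s2) && length(advanced) > 1) {
    s2_args <- list(
      n_testers = stage2_cfg$n_testers %||% 3L,
      sigma2_tester = stage2_cfg$sigma2_tester %||% 0.37,
      sigma2_gxt = stage2_cfg$sigma2_gxt %||% 0.23,
      n_trials = stage2_cfg$n_trials %||% cfg$n_trials,
      seed = seed + 4L)
    s2_cfg <- do.call(sim_config, utils::modifyList(as.list(unclass(cfg))[
      setdiff(names(unclass(cfg)), "seed")], s2_args))
    stage2 <- simulate_trials(program, config = s2_cfg, entries = advanced,
                              seed = seed + 5L)
    # balanced simulated trials: hybrid means per management are the BLUEs
    agg <- stats::aggregate(stage2[[cfg$trait]],
                            by = list(entry = stage2$entry,
                                      line = stage2$line,
                                      cohort = stage2$cohort,
                                      management = stage2$management),
                            FUN = mean)
    names(agg)[names(agg) == "x"] <- "value"
    comparison <- comparison_table(agg, f = f_sel)
    advancement <- lapply(split(agg, agg$management), function(am) {
      hyb <- am[am$cohort != "check", ]
      advancement_rates(stats::setNames(hyb$value, hyb$entry), hyb$cohort,
                        f = f_sel)
    })
  }

  ledger_path <- config$cost_ledger %||%
    system.file("extdata", "stage1_cost_ledger.csv", package = "maizegs")
  costs <- cost_report(read_cost_ledger(ledger_path))

  res <- list(program = program, pheno = pheno, blues = blues, grm = grm,
              genomic_fit_ww = fit_ww, genomic_fit_ws = fit_ws, gebv = gebv,
              selection = list(PS = ps_sel, GS = gs_sel, advanced = advanced),
              cv = cv_res, stage2 = stage2, comparison = comparison,
              advancement = advancement, costs = costs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(program$genotypes, file.path(out_dir, "genotypes.csv"))
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.csv"))
    utils::write.csv(blues, file.path(out_dir, "blues.csv"), row.names = FALSE)
    if (!is.null(gebv))
      utils::write.csv(gebv, file.path(out_dir, "gebv.csv"), row.names = FALSE)
    if (!is.null(cv_res))
      utils::write.csv(as.data.frame(cv_res), file.path(out_dir, "cv_accuracy.csv"),
                       row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(as.data.frame(comparison),
                       file.path(out_dir, "comparison_table.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(quantity = c("ps_total", "gs_total", "ratio"),
                                value = unlist(costs)),
                     file.path(out_dir, "costs.csv"), row.names = FALSE)
  }
  res
}

#' Per-environment entry BLUEs from plot data
#'
#' Fits [fit_single_location()] with genotype fixed in each environment and
#' returns the entry BLUEs of the genotyped lines (checks are dropped: they
#' carry no marker data).
#'
#' @param pheno Plot-level phenotype table.
#' @param trait Trait column name.
#' @param keep_checks Keep check entries in the output (default `FALSE`).
#' @return Data frame `line`, `env`, `management`, `value`, `se`.
#' @export
stage_blues <- function(pheno, trait, keep_checks = FALSE) {
  out <- lapply(split(pheno, pheno$location), function(pe) {
    fit <- fit_single_location(pe, trait, genotype_role = "fixed")
    b <- fit$blues
    co <- pe$cohort[match(b$entry, pe$entry)]
    data.frame(line = b$entry, env = pe$location[1],
               management = pe$management[1], value = b$blue, se = b$se,
               cohort = co, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!keep_checks) res <- res[res$cohort != "check", , drop = FALSE]
  rownames(res) <- NULL
  res
}
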