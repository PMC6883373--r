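# Repeated random k-fold cross-validation of genomic prediction accuracy.
#
# Partitioning is at the LINE level: a held-out line is unobserved in every
# environment. Within a repeat the five test-fold prediction vectors are
# concatenated and a single Pearson correlation with the observed values is
# computed per environment; the accuracy table reports the mean and sd of
# that correlation across repeats.

#' Random fold plan for line-level cross-validation
#'
#' @param line_ids Character vector of line IDs.
#' @param k Number of folds (default 5).
#' @param n_repeats Number of random repeats (default 100).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return Data frame `repeat_ix`, `fold`, `line`; within each repeat the
#'   folds partition the lines exactly and fold sizes differ by at most 1.
#' @export
make_folds <- function(line_ids, k = 5, n_repeats = 100, seed) {
  line_ids <- as.character(line_ids)
  n <- length(line_ids)
  if (anyDuplicated(line_ids)) stop_("duplicate line IDs")
  if (k < 2 || k > n) stop_("k must satisfy 2 <= k <= number of lines")
  if (n_repeats < 1) stop_("n_repeats must be >= 1")
  plan <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_repeats), function(rep_ix) {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
      data.frame(repeat_ix = rep_ix, fold = fold, line = line_ids,
                 stringsAsFactors = FALSE)
    }))
  })
  attr(plan, "k") <- k
  attr(plan, "seed") <- seed
  plan
}

default_gblup_fitter <- function(iters = 1500L, burnin = 500L, thin = 2L,
                                 variant = "auto") {
  function(train_blues, grm, test_lines, seed) {
    fit <- fit_genomic(train_blues, grm, variant = variant, iters = iters,
                       burnin = burnin, thin = thin, seed = seed)
    predict_gebv(fit, test_lines, what = "env")
  }
}

#' Run genomic cross-validation over a fold plan
#'
#' For each repeat and fold, the model is trained on the remaining folds via
#' [fit_genomic()] and the held-out lines are predicted with
#' [predict_gebv()]; test-fold predictions are concatenated within the
#' repeat and correlated with the observed values per environment.
#'
#' @param blues Data frame `line`, `env`, `value` of observed line means.
#' @param grm A [build_grm()] object covering all lines in the plan.
#' @param plan Fold plan from [make_folds()].
#' @param fitter Prediction backend: a
#'   `function(train_blues, grm, test_lines, seed)` returning a data frame
#'   `line`, `env`, `gebv`. Defaults to the Gibbs G-BLUP with chain settings
#'   `iters`/`burnin` sized for repeated fitting.
#' @param iters,burnin,thin Chain settings passed to the default fitter.
#' @param variant Model variant passed to [fit_genomic()].
#' @param min_test Minimum test observations per environment for a
#'   correlation to be recorded in a repeat (default 3).
#' @return Data frame of class `accuracy_table`: `env`, `r_mean`, `r_sd`,
#'   `n_repeats`, with per-repeat correlations in `attr(, "per_repeat")`.
#' @export
run_cv <- function(blues, grm, plan, fitter = NULL,
                   iters = 1500L, burnin = 500L, thin = 2L,
                   variant = "auto", min_test = 3L) {
  if (!"env" %in% names(blues)) blues$env <- "E1"
  lines_all <- unique(plan$line)
  if (!all(lines_all %in% blues$line))
    stop_("plan contains lines without observed values")
  G <- grm_matrix(grm)
  if (!all(lines_all %in% rownames(G)))
    stop_("plan contains lines absent from the GRM")
  if (is.null(fitter))
    fitter <- default_gblup_fitter(iters, burnin, thin, variant)
  k <- attr(plan, "k") %||% max(plan$fold)
  base_seed <- (attr(plan, "seed") %||% 0) %% 1e6
  envs <- sort(unique(blues$env))
  reps <- sort(unique(plan$repeat_ix))
  obs_key <- stats::setNames(blues$value, paste(blues$line, blues$env))

  per_rep <- matrix(NA_real_, length(reps), length(envs),
                    dimnames = list(NULL, envs))
  for (ri in seq_along(reps)) {
    pr <- plan[plan$repeat_ix == reps[ri], , drop = FALSE]
    preds <- vector("list", k)
    for (f in sort(unique(pr$fold))) {
      test_lines <- pr$line[pr$fold == f]
      train_blues <- blues[!blues$line %in% test_lines &
                             blues$line %in% pr$line, , drop = FALSE]
      fold_seed <- (base_seed * 1000 + reps[ri] * k + f) %% .Machine$integer.max
      preds[[f]] <- fitter(train_blues, grm, test_lines, seed = fold_seed)
    }
    pred <- do.call(rbind, preds)
    pred$obs <- obs_key[paste(pred$line, pred$env)]
    for (e in envs) {
      pe <- pred[pred$env == e & is.finite(pred$obs), , drop = FALSE]
      if (nrow(pe) < min_test || stats::sd(pe$obs) == 0 ||
          stats::sd(pe$gebv) == 0) {
        warn_("repeat %d, environment %s: too few usable test observations; accuracy recorded as NA",
              reps[ri], e)
      } else {
        per_rep[ri, e] <- stats::cor(pe$gebv, pe$obs)
      }
    }
  }
  out <- data.frame(env = envs,
                    r_mean = colMeans(per_rep, na.rm = TRUE),
                    r_sd = apply(per_rep, 2, stats::sd, na.rm = TRUE),
                    n_repeats = colSums(!is.na(per_rep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_repeat") <- per_rep
  class(out) <- c("accuracy_table", class(out))
  out
}

#' Within- and across-tester cross-validation scenarios
#'
#' Within-tester accuracy restricts the cross-validation to each tester's
#' lines separately; across-tester accuracy pools all lines after centering
#' the observed values on the per-tester (per-environment) mean, so that
#' tester main effects do not inflate the correlation.
#'
#' @param blues Data frame `line`, `env`, `value`, `tester`.
#' @param grm A [build_grm()] object.
#' @param k,n_repeats,seed Fold-plan settings (per-tester plans are derived
#'   from `seed`).
#' @param ... Passed on to [run_cv()].
#' @return Data frame of class `accuracy_table` with columns `scenario`,
#'   `tester`, `env`, `r_mean`, `r_sd`, `n_repeats`.
#' @export
tester_scenarios <- function(blues, grm, k = 5, n_repeats = 10, seed, ...) {
  if (!"tester" %in% names(blues)) stop_("blues needs a 'tester' column")
  if (!"env" %in% names(blues)) blues$env <- "E1"
  testers <- sort(unique(blues$tester))
  out <- list()
  for (ti in seq_along(testers)) {
    tb <- blues[blues$tester == testers[ti], , drop = FALSE]
    t_lines <- unique(tb$line)
    if (length(t_lines) < k) {
      warn_("tester %s has fewer lines (%d) than folds (%d); skipped",
            testers[ti], length(t_lines), k)
      next
    }
    plan <- make_folds(t_lines, k, n_repeats, seed = seed + ti)
    acc <- run_cv(tb, grm, plan, ...)
    acc$scenario <- "within-tester"
    acc$tester <- testers[ti]
    out[[length(out) + 1L]] <- as.data.frame(acc)
  }
  # across testers: tester-mean-centered values, pooled lines
  ctr <- stats::ave(blues$value, paste(blues$tester, blues$env))
  pooled <- data.frame(line = blues$line, env = blues$env,
                       value = blues$value - ctr, stringsAsFactors = FALSE)
  pooled <- stats::aggregate(value ~ line + env, pooled, mean)
  plan <- make_folds(unique(pooled$line), k, n_repeats, seed = seed)
  acc <- run_cv(pooled, grm, plan, ...)
  acc$scenario <- "across-testers"
  acc$tester <- "all"
  out[[length(out) + 1L]] <- as.data.frame(acc)
  res <- do.call(rbind, out)
  res <- res[, c("scenario", "tester", "env", "r_mean", "r_sd", "n_repeats")]
  class(res) <- c("accuracy_table", class(res))
  res
}

#' Format an accuracy table in mean +/- sd style
#'
#' @param x An `accuracy_table`.
#' @param digits Decimal places (default 2).
#' @return Character vector like `"0.41 ± 0.09"`.
#' @export
format_accuracy <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), x$r_mean, x$r_sd)
}
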