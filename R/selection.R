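# Advancement rules and stage-II cohort comparisons.
#
# Stage-I advancement: lines with a criterion value (BLUE for phenotyped
# lines, GEBV for predicted lines) strictly above the cohort mean advance.
# Stage-II comparisons operate on hybrid (line x tester) means: per cohort
# and management, the mean of all hybrids, of the top fraction, the best
# hybrid, and integer percent improvements over the commercial checks.

#' Select entries with values strictly above the cohort mean
#'
#' @param values Named numeric vector of criterion values (BLUEs or GEBVs).
#' @param rule_tag Label recorded with each decision.
#' @return Data frame `entry`, `value`, `selected`, `rule`. If all values are
#'   equal the selection is empty (with a warning).
#' @export
select_above_average <- function(values, rule_tag = "above-average") {
  v <- values[is.finite(values)]
  if (!length(v)) stop_("no finite criterion values")
  if (is.null(names(v))) names(v) <- sprintf("E%d", seq_along(v))
  sel <- v > mean(v)
  if (!any(sel)) warn_("all values at or below the mean: empty selection")
  data.frame(entry = names(v), value = unname(v), selected = unname(sel),
             rule = rule_tag, stringsAsFactors = FALSE)
}

#' Select the top fraction of entries
#'
#' The number selected is `round_half_up(f * N)`; ties are broken by stable
#' entry order.
#'
#' @param scores Named numeric vector.
#' @param f Fraction in (0, 1].
#' @return Character vector of selected entry IDs (highest scores first).
#' @examples
#' length(top_fraction(setNames(rnorm(526), paste0("H", 1:526)), 0.15))  # 79
#' @export
top_fraction <- function(scores, f = 0.15) {
  if (!length(scores)) stop_("no scores supplied")
  if (!is.numeric(f) || f <= 0 || f > 1) stop_("f must be in (0, 1]")
  if (any(!is.finite(scores))) stop_("scores must be finite")
  if (is.null(names(scores))) names(scores) <- sprintf("E%d", seq_along(scores))
  n_sel <- round_half_up(f * length(scores))
  ord <- order(-scores, seq_along(scores))   # stable tie-break by input order
  names(scores)[ord[seq_len(n_sel)]]
}

#' Integer percent improvement of a candidate over a reference
#'
#' `round_half_up(100 * (candidate / reference - 1))`; may be negative.
#'
#' @param candidate_mean,reference_mean Trait means; the reference must be
#'   positive.
#' @return Integer percent.
#' @examples
#' percent_improvement(11.7, 8.4)  # 39
#' @export
percent_improvement <- function(candidate_mean, reference_mean) {
  if (any(reference_mean <= 0)) stop_("reference mean must be positive")
  round_half_up(100 * (candidate_mean / reference_mean - 1))
}

#' Stage-II comparison table of selection cohorts versus checks
#'
#' @param stage2 Data frame of hybrid means with columns `entry`, `cohort`
#'   (`"PS"`, `"GS"` or `"check"`), `management` and `value` (t/ha). Checks
#'   never enter cohort statistics.
#' @param f Top fraction (default 0.15).
#' @return Data frame of class `comparison_table` with one row per cohort x
#'   management: `n_hybrids`, `mean_all`, `mean_top`, `best`, `checks_mean`,
#'   `best_check`, and the four integer percent improvement cells
#'   `top_vs_checks_mean`, `top_vs_best_check`, `best_vs_checks_mean`,
#'   `best_vs_best_check`.
#' @export
comparison_table <- function(stage2, f = 0.15) {
  need <- c("entry", "cohort", "management", "value")
  miss <- setdiff(need, names(stage2))
  if (length(miss)) stop_("stage2 is missing column(s): %s",
                          paste(miss, collapse = ", "))
  stage2 <- stage2[is.finite(stage2$value), , drop = FALSE]
  cohorts <- setdiff(sort(unique(stage2$cohort)), "check")
  if (!length(cohorts)) stop_("no selection cohorts present")
  mgs <- sort(unique(stage2$management))
  rows <- list()
  for (mg in mgs) {
    sm <- stage2[stage2$management == mg, , drop = FALSE]
    chk <- sm$value[sm$cohort == "check"]
    if (!length(chk)) stop_("management %s has no checks", mg)
    for (co in cohorts) {
      v <- sm$value[sm$cohort == co]
      if (!length(v)) next
      names(v) <- sm$entry[sm$cohort == co]
      top <- v[top_fraction(v, f)]
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = co, management = mg, n_hybrids = length(v),
        mean_all = mean(v), mean_top = mean(top), best = max(v),
        checks_mean = mean(chk), best_check = max(chk),
        top_vs_checks_mean = percent_improvement(mean(top), mean(chk)),
        top_vs_best_check = percent_improvement(mean(top), max(chk)),
        best_vs_checks_mean = percent_improvement(max(v), mean(chk)),
        best_vs_best_check = percent_improvement(max(v), max(chk)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  out
}

#' @export
print.comparison_table <- function(x, digits = 1, ...) {
  cat("Stage-II cohort comparison (t/ha; improvements in integer %)\n")
  df <- as.data.frame(x)
  num <- c("mean_all", "mean_top", "best", "checks_mean", "best_check")
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Advancement-rate shares of the selection cohorts
#'
#' Selects the top fraction of the pooled (check-free) hybrid set and reports
#' each cohort's integer percent share of the selected hybrids.
#'
#' @param scores Named numeric vector of pooled hybrid scores.
#' @param cohorts Character vector of cohort labels aligned with `scores`.
#' @param f Top fraction (default 0.15).
#' @return Named integer vector of percent shares (one per cohort level),
#'   with the selected count in `attr(, "n_selected")`.
#' @export
advancement_rates <- function(scores, cohorts, f = 0.15) {
  if (length(scores) != length(cohorts)) stop_("scores and cohorts differ in length")
  if (is.null(names(scores))) names(scores) <- sprintf("H%d", seq_along(scores))
  keep <- cohorts != "check"
  scores <- scores[keep]; cohorts <- cohorts[keep]
  if (length(unique(cohorts)) < 1) stop_("no cohorts to compare")
  sel <- top_fraction(scores, f)
  if (!length(sel)) stop_("empty selection")
  sel_cohort <- cohorts[match(sel, names(scores))]
  shares <- vapply(sort(unique(cohorts)), function(co)
    round_half_up(100 * sum(sel_cohort == co) / length(sel)), numeric(1))
  attr(shares, "n_selected") <- length(sel)
  attr(shares, "n_by_cohort") <- table(factor(sel_cohort, sort(unique(cohorts))))
  shares
}

#' Cohort share of an advanced set from counts
#'
#' Arithmetic helper behind [advancement_rates()]: the integer percent share
#' of one cohort among the advanced hybrids.
#'
#' @param n_cohort_selected,n_selected Counts of advanced hybrids.
#' @return Integer percent.
#' @examples
#' cohort_share(64, 157)  # 41
#' @export
cohort_share <- function(n_cohort_selected, n_selected) {
  if (n_selected <= 0) stop_("n_selected must be positive")
  if (n_cohort_selected < 0 || n_cohort_selected > n_selected)
    stop_("n_cohort_selected must be between 0 and n_selected")
  round_half_up(100 * n_cohort_selected / n_selected)
}
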