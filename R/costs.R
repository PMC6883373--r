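# Activity-based cost accounting for phenotypic vs genomic selection.
#
# A cost ledger is a data frame with one row per breeding activity and the
# columns: strategy, activity, cost_per_entry (US$), n_entries, reps_per_site,
# rows_per_site, n_sites. The cost of an activity is the plain product of its
# five numeric fields, matching spreadsheet budgeting practice.

ledger_cols <- c("cost_per_entry", "n_entries", "reps_per_site",
                 "rows_per_site", "n_sites")

#' Cost of a single breeding activity
#'
#' @param activity A one-row data frame (or list) with numeric fields
#'   `cost_per_entry`, `n_entries`, `reps_per_site`, `rows_per_site`,
#'   `n_sites`, all non-negative.
#' @return Cost in US$: the product of the five fields. Zeros are allowed and
#'   propagate to a zero cost.
#' @examples
#' activity_cost(list(cost_per_entry = 5, n_entries = 1492,
#'                    reps_per_site = 2, rows_per_site = 2, n_sites = 4))
#' @export
activity_cost <- function(activity) {
  v <- vapply(ledger_cols, function(cl) {
    x <- activity[[cl]]
    if (is.null(x) || length(x) != 1L || !is.finite(as.numeric(x)))
      stop_("activity field '%s' must be a single finite number", cl)
    as.numeric(x)
  }, numeric(1))
  if (any(v < 0)) stop_("activity fields must be non-negative")
  prod(v)
}

#' Total cost of a selection strategy
#'
#' Sums [activity_cost()] over the rows of a cost ledger. The total is
#' additive and invariant to row order; an empty ledger costs 0.
#'
#' @param ledger Data frame of activities (see [read_cost_ledger()]).
#' @param strategy Optional strategy label; when given and the ledger has a
#'   `strategy` column, only matching rows are summed.
#' @return Total cost in US$.
#' @export
strategy_cost <- function(ledger, strategy = NULL) {
  if (is.null(ledger) || nrow(ledger) == 0L) return(0)
  if (!is.null(strategy)) {
    if (!"strategy" %in% names(ledger))
      stop_("ledger has no 'strategy' column")
    ledger <- ledger[ledger$strategy == strategy, , drop = FALSE]
  }
  if (nrow(ledger) == 0L) return(0)
  if ("activity" %in% names(ledger)) {
    key <- if ("strategy" %in% names(ledger))
      paste(ledger$strategy, ledger$activity) else ledger$activity
    if (anyDuplicated(key)) stop_("duplicate activity labels within a strategy")
  }
  sum(vapply(seq_len(nrow(ledger)),
             function(i) activity_cost(ledger[i, , drop = FALSE]),
             numeric(1)))
}

#' Cost ratio of genomic to phenotypic selection
#'
#' @param gs_total,ps_total Strategy totals in US$; `ps_total` must be > 0.
#' @return `gs_total / ps_total` rounded to 2 decimals.
#' @examples
#' cost_ratio(91870, 134280)  # 0.68
#' @export
cost_ratio <- function(gs_total, ps_total) {
  if (!is.numeric(ps_total) || ps_total <= 0)
    stop_("ps_total must be a positive number")
  if (gs_total < 0) stop_("gs_total must be non-negative")
  round(gs_total / ps_total, 2)
}

#' Read a cost ledger CSV
#'
#' Expected columns: `strategy`, `activity`, `cost_per_entry`, `n_entries`,
#' `reps_per_site`, `rows_per_site`, `n_sites`. A ledger for the program's
#' stage-I budget is shipped in
#' `system.file("extdata", "stage1_cost_ledger.csv", package = "maizegs")`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of activities.
#' @export
read_cost_ledger <- function(path) {
  if (!file.exists(path)) stop_("cost ledger file not found: %s", path)
  led <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("strategy", "activity", ledger_cols), names(led))
  if (length(miss))
    stop_("cost ledger is missing column(s): %s", paste(miss, collapse = ", "))
  for (cl in ledger_cols) {
    if (!is.numeric(led[[cl]])) stop_("column '%s' must be numeric", cl)
    if (any(!is.finite(led[[cl]])) || any(led[[cl]] < 0))
      stop_("column '%s' must be finite and non-negative", cl)
  }
  led
}

#' Cost report for a two-strategy ledger
#'
#' @param ledger Data frame with a `strategy` column containing "PS" and "GS"
#'   rows.
#' @return List with `ps_total`, `gs_total` (US$) and `ratio` (GS:PS, 2 dp).
#' @export
cost_report <- function(ledger) {
  ps <- strategy_cost(ledger, "PS")
  gs <- strategy_cost(ledger, "GS")
  list(ps_total = ps, gs_total = gs, ratio = cost_ratio(gs, ps))
}
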