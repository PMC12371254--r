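#' Call risk cells at a fixed index threshold
#'
#' A cell is a risk cell iff its index is strictly greater than the
#' threshold (a cell sitting exactly at the threshold is not called).
#' The default 0.89 is the fixed probability-scale cutoff used for beta
#' cells in real-cohort analyses.
#'
#' @param indexes a [compute_disease_index()] result.
#' @param threshold index cutoff in `[0, 1]`.
#' @return a `RiskCall` data.frame: `cell_id`, `is_risk`, `threshold`,
#'   `method`, `cell_type`.
#' @export
call_risk_fixed <- function(indexes, threshold = 0.89) {
  if (threshold < 0 || threshold > 1)
    stop_value("threshold must be in [0,1]; got %s", format(threshold))
  data.frame(cell_id = indexes$cell_id,
             is_risk = indexes$index > threshold,
             threshold = threshold,
             method = "fixed",
             cell_type = indexes$cell_type,
             stringsAsFactors = FALSE)
}

#' Call risk cells above an empirical index quantile
#'
#' The threshold is the `q`-quantile of the indexes pooled over all cells
#' of the type (linear-interpolation quantile, R type 7), and the same
#' strict-greater rule as [call_risk_fixed()] is applied, so quantile
#' calling at `q` equals fixed calling at the computed quantile value.
#'
#' @param indexes a [compute_disease_index()] result with >= 2 cells.
#' @param q quantile in `(0, 1)`.
#' @return a `RiskCall` data.frame (method `"quantile"`).
#' @export
call_risk_quantile <- function(indexes, q) {
  if (q <= 0 || q >= 1) stop_value("q must be in (0,1); got %s", format(q))
  if (nrow(indexes) < 2) stop_value("need at least 2 cells for quantile calling")
  thr <- unname(stats::quantile(indexes$index, probs = q, type = 7))
  out <- data.frame(cell_id = indexes$cell_id,
                    is_risk = indexes$index > thr,
                    threshold = thr,
                    method = "quantile",
                    cell_type = indexes$cell_type,
                    stringsAsFactors = FALSE)
  if (!any(out$is_risk) && stats::sd(indexes$index) == 0)
    warning("all indexes are equal; zero risk cells called")
  out
}

# per-donor risk proportions at a given threshold (strict >)
.proportions_at <- function(indexes, threshold) {
  risk <- indexes$index > threshold
  tab <- tapply(risk, indexes$donor_id, mean)
  data.frame(donor_id = names(tab), proportion = as.numeric(tab),
             stringsAsFactors = FALSE)
}

#' Choose a risk threshold by sliding-window scan of donor separation
#'
#' Scans a grid of candidate thresholds; at each, computes per-donor risk
#' proportions and the Kruskal-Wallis statistic of those proportions across
#' disease-state groups. The chosen threshold maximizes the statistic
#' subject to an overall risk fraction of at least `min_risk_fraction`
#' (which rules out the degenerate "flag nothing" optimum); exact ties are
#' broken toward the largest threshold. The criterion uses all three states
#' and is rank-based; it is this package's construction of the
#' sliding-window idea.
#'
#' @param indexes a [compute_disease_index()] result.
#' @param cohort the cohort the indexes came from (supplies donor states);
#'   must contain >= 2 disease states among the indexed donors.
#' @param grid sorted vector of candidate thresholds within `[0, 1]`
#'   (default `seq(0.05, 0.95, by = 0.05)`).
#' @param min_risk_fraction minimum overall fraction of cells called risk
#'   for a threshold to be feasible (default 0.01).
#' @return list with `threshold` (chosen), `risk` (the `RiskCall`
#'   data.frame at it, method `"sliding_window"`), and `trace` (one row per
#'   grid value: threshold, Kruskal-Wallis statistic, overall risk
#'   fraction, feasibility).
#' @export
call_risk_sliding_window <- function(indexes, cohort,
                                     grid = seq(0.05, 0.95, by = 0.05),
                                     min_risk_fraction = 0.01) {
  if (any(grid < 0) || any(grid > 1)) stop_value("grid must lie within [0,1]")
  grid <- sort(grid)
  donors <- cohort$donors[cohort$donors$donor_id %in% indexes$donor_id, ]
  if (length(unique(donors$state)) < 2)
    stop_value("sliding-window selection needs >= 2 disease states; found %d",
               length(unique(donors$state)))
  trace <- data.frame(threshold = grid, statistic = NA_real_,
                      overall_risk_fraction = NA_real_, feasible = FALSE)
  for (i in seq_along(grid)) {
    props <- .proportions_at(indexes, grid[i])
    st <- donors$state[match(props$donor_id, donors$donor_id)]
    stat <- if (stats::sd(props$proportion) == 0) 0 else
      unname(stats::kruskal.test(props$proportion, factor(st))$statistic)
    trace$statistic[i] <- stat
    trace$overall_risk_fraction[i] <- mean(indexes$index > grid[i])
    trace$feasible[i] <- trace$overall_risk_fraction[i] >= min_risk_fraction
  }
  if (!any(trace$feasible))
    stop_value("no grid threshold keeps the overall risk fraction >= %s",
               format(min_risk_fraction))
  feas <- which(trace$feasible)
  best <- max(feas[trace$statistic[feas] == max(trace$statistic[feas])])
  thr <- grid[best]
  risk <- data.frame(cell_id = indexes$cell_id,
                     is_risk = indexes$index > thr,
                     threshold = thr,
                     method = "sliding_window",
                     cell_type = indexes$cell_type,
                     stringsAsFactors = FALSE)
  list(threshold = thr, risk = risk, trace = trace)
}

#' Threshold sensitivity analysis
#'
#' For each grid threshold, reports the per-state mean donor risk
#' proportion and the three pairwise staging AUCs computed on per-donor
#' proportions ([roc_auc()]), to show how stable staging is to the choice
#' of cutoff.
#'
#' @inheritParams call_risk_sliding_window
#' @return data.frame with one row per grid value: `threshold`,
#'   `mean_prop_nd`, `mean_prop_pret2d`, `mean_prop_t2d`, `auc_t2d_vs_nd`,
#'   `auc_t2d_vs_pret2d`, `auc_pret2d_vs_nd` (AUC `NA` when a state is
#'   absent).
#' @export
threshold_sensitivity <- function(indexes, cohort,
                                  grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(grid < 0) || any(grid > 1)) stop_value("grid must lie within [0,1]")
  grid <- sort(grid)
  donors <- cohort$donors[cohort$donors$donor_id %in% indexes$donor_id, ]
  out <- data.frame(threshold = grid,
                    mean_prop_nd = NA_real_, mean_prop_pret2d = NA_real_,
                    mean_prop_t2d = NA_real_,
                    auc_t2d_vs_nd = NA_real_, auc_t2d_vs_pret2d = NA_real_,
                    auc_pret2d_vs_nd = NA_real_)
  pair_auc <- function(props, st, hi, lo) {
    sel <- st %in% c(hi, lo)
    if (length(unique(st[sel])) < 2) return(NA_real_)
    roc_auc(props[sel], as.integer(st[sel] == hi))$auc
  }
  for (i in seq_along(grid)) {
    pr <- .proportions_at(indexes, grid[i])
    st <- donors$state[match(pr$donor_id, donors$donor_id)]
    means <- tapply(pr$proportion, factor(st, levels = 0:2), mean)
    out$mean_prop_nd[i] <- means[["0"]]
    out$mean_prop_pret2d[i] <- means[["1"]]
    out$mean_prop_t2d[i] <- means[["2"]]
    out$auc_t2d_vs_nd[i] <- pair_auc(pr$proportion, st, 2L, 0L)
    out$auc_t2d_vs_pret2d[i] <- pair_auc(pr$proportion, st, 2L, 1L)
    out$auc_pret2d_vs_nd[i] <- pair_auc(pr$proportion, st, 1L, 0L)
  }
  out
}
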