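#' Aggregate risk calls to per-donor risk-cell proportions
#'
#' One profile per donor owning at least one analyzed cell; donors of the
#' cohort with zero cells of the analyzed type are omitted (and reported
#' via a message).
#'
#' @param risk a `RiskCall` data.frame (see [call_risk_fixed()]).
#' @param cohort the cohort the calls came from.
#' @return `DonorRiskProfile` data.frame: `donor_id`, `state`, `n_cells`,
#'   `n_risk`, `proportion`.
#' @export
donor_risk_proportions <- function(risk, cohort) {
  hit <- match(risk$cell_id, cohort$cells$cell_id)
  if (anyNA(hit))
    stop_integrity("risk call(s) for cell(s) absent from the cohort: %s",
                   paste(utils::head(risk$cell_id[is.na(hit)], 5), collapse = ", "))
  donor <- cohort$cells$donor_id[hit]
  n_cells <- tapply(rep(1L, nrow(risk)), donor, sum)
  n_risk <- tapply(risk$is_risk, donor, sum)
  ids <- names(n_cells)
  omitted <- setdiff(cohort$donors$donor_id, ids)
  if (length(omitted))
    message(sprintf("donor_risk_proportions: omitting %d donor(s) with no analyzed cells: %s",
                    length(omitted), paste(omitted, collapse = ", ")))
  data.frame(donor_id = ids,
             state = cohort$donors$state[match(ids, cohort$donors$donor_id)],
             n_cells = as.integer(n_cells),
             n_risk = as.integer(n_risk),
             proportion = as.numeric(n_risk / n_cells),
             stringsAsFactors = FALSE)
}

#' Stage a donor from its risk-cell proportion by rule bands
#'
#' `p < cut_low` is ND, `cut_low <= p <= cut_high` is preT2D (a closed
#' band), and `p > cut_high` is T2D. The defaults are the 10% / 20% bands
#' used for beta cells.
#'
#' @param p risk-cell proportion(s) in `[0, 1]` (vectorized).
#' @param cut_low,cut_high band edges, `0 <= cut_low < cut_high <= 1`.
#' @return integer state code(s): 0 (ND), 1 (preT2D), 2 (T2D).
#' @export
stage_by_rule <- function(p, cut_low = 0.10, cut_high = 0.20) {
  if (!(cut_low < cut_high) || cut_low < 0 || cut_high > 1)
    stop_value("need 0 <= cut_low < cut_high <= 1")
  if (any(p < 0 | p > 1)) stop_value("proportions must lie in [0,1]")
  ifelse(p < cut_low, 0L, ifelse(p > cut_high, 2L, 1L))
}

#' Pairwise maximum-margin staging on the risk-cell proportion
#'
#' For each state pair (T2D vs ND, T2D vs preT2D, preT2D vs ND) fits a
#' linear support vector machine on the single proportion feature and
#' evaluates it by leave-one-donor-out cross-validation; held-out decision
#' scores feed [roc_auc()]. On one feature any maximum-margin classifier
#' reduces to a threshold, so results are insensitive to SVM tuning.
#'
#' @param profiles a [donor_risk_proportions()] result with >= 2 donors in
#'   each compared state.
#' @return list with `pairs` (data.frame: `pair`, `auc`, `n`) and `scores`
#'   (per pair, a data.frame of donor_id, label, held-out decision score,
#'   oriented so larger = more diseased).
#' @export
fit_stage_classifier <- function(profiles) {
  pairs <- list(t2d_vs_nd = c(2L, 0L), t2d_vs_pret2d = c(2L, 1L),
                pret2d_vs_nd = c(1L, 0L))
  res <- data.frame(pair = names(pairs), auc = NA_real_, n = NA_integer_)
  scores <- list()
  for (j in seq_along(pairs)) {
    hi <- pairs[[j]][1]; lo <- pairs[[j]][2]
    sel <- profiles[profiles$state %in% c(hi, lo), , drop = FALSE]
    for (st in c(hi, lo))
      if (sum(sel$state == st) < 2)
        stop_value("state %s has fewer than 2 donors for pair %s",
                   state_label(st), names(pairs)[j])
    y <- factor(as.integer(sel$state == hi), levels = c(0, 1))
    x <- sel$proportion
    dec <- vapply(seq_len(nrow(sel)), function(i) {
      fit <- e1071::svm(x = matrix(x[-i], ncol = 1), y = y[-i],
                        kernel = "linear", scale = TRUE)
      d <- attr(stats::predict(fit, matrix(x[i], ncol = 1),
                               decision.values = TRUE), "decision.values")
      # orient so that larger decision value = the diseased class, using the
      # training cells' own decision values as the reference
      dtr <- attr(stats::predict(fit, matrix(x[-i], ncol = 1),
                                 decision.values = TRUE), "decision.values")
      ytr <- y[-i]
      sgn <- if (mean(dtr[ytr == "1"]) >= mean(dtr[ytr == "0"])) 1 else -1
      sgn * as.numeric(d)
    }, numeric(1))
    res$auc[j] <- roc_auc(dec, as.integer(sel$state == hi))$auc
    res$n[j] <- nrow(sel)
    scores[[names(pairs)[j]]] <- data.frame(donor_id = sel$donor_id,
                                            label = as.integer(sel$state == hi),
                                            score = dec,
                                            stringsAsFactors = FALSE)
  }
  list(pairs = res, scores = scores)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney concordance probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from mid-ranks; the
#' ROC is the nondecreasing step curve from (0,0) to (1,1) traced by
#' sweeping a strict-greater threshold over the unique scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return list with `curve` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(y) != length(scores)) stop_value("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_value("both classes must be present")
  r <- rank(scores)   # mid-ranks handle ties as 0.5 concordance
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1)))
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified bootstrap percentile confidence interval for an AUC
#'
#' Resamples donors within each class (so every replicate keeps both
#' classes), recomputes the AUC, and returns the percentile interval.
#' Deterministic given `seed`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with `lower`, `upper`, `auc` (point estimate), `n_boot`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = 1L) {
  y <- as.integer(labels)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) stop_value("both classes must be present")
  point <- roc_auc(scores, y)$auc
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (attempt in 1:10) {
        j1 <- sample(i1, replace = TRUE); j0 <- sample(i0, replace = TRUE)
        s <- c(scores[j1], scores[j0])
        lab <- c(rep(1L, length(j1)), rep(0L, length(j0)))
        if (length(unique(lab)) == 2) return(roc_auc(s, lab)$auc)
      }
      warning("bootstrap replicate skipped: single-class resample")
      NA_real_
    }, numeric(1))
  })
  qs <- stats::quantile(aucs, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], auc = point, n_boot = n_boot)
}

#' Pearson association between a risk measure and a clinical covariate
#'
#' Pairwise-complete: pairs with a missing value in either variable are
#' dropped and the n actually used is reported. The p-value is the
#' two-sided t-test on `t = r * sqrt((n-2) / (1-r^2))` with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (e.g. per-donor risk
#'   proportion and HbA1c); >= 3 complete pairs and nonzero variance in
#'   both are required.
#' @return list with `r`, `p`, `n` (complete pairs used).
#' @export
pearson_assoc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_value("need >= 3 complete pairs; have %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_value("zero variance in x or y after dropping missing pairs")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare risk-cell proportions between disease-state groups
#'
#' Two-sided Wilcoxon rank-sum tests for all three state pairs, with
#' Benjamini-Hochberg adjustment across the three p-values. Exact
#' enumeration is used when both groups have <= 8 donors and the
#' proportions are tie-free; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param profiles a [donor_risk_proportions()] result with >= 2 donors per
#'   state.
#' @return data.frame: `pair`, `W`, `p`, `p_adj`.
#' @export
group_compare <- function(profiles) {
  pairs <- list(t2d_vs_nd = c(2L, 0L), t2d_vs_pret2d = c(2L, 1L),
                pret2d_vs_nd = c(1L, 0L))
  out <- data.frame(pair = names(pairs), W = NA_real_, p = NA_real_)
  for (j in seq_along(pairs)) {
    a <- profiles$proportion[profiles$state == pairs[[j]][1]]
    b <- profiles$proportion[profiles$state == pairs[[j]][2]]
    if (length(a) < 2 || length(b) < 2)
      stop_value("pair %s: each group needs >= 2 donors", names(pairs)[j])
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                             correct = TRUE)
    out$W[j] <- unname(wt$statistic)
    out$p[j] <- wt$p.value
  }
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up with monotonicity enforcement; the output preserves
#' the input order and is elementwise >= the input.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_value("p-values must lie in [0,1] with no NA")
  stats::p.adjust(pvals, method = "BH")
}
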