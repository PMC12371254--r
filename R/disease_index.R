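#' Configuration for the pseudo disease-index model
#'
#' The scorer is an elastic-net-regularized binomial linear model on
#' log-normalized (optionally HVG-restricted) expression with
#' inverse-frequency class weights, trained inside donor-grouped
#' cross-validation folds and sharpened by self-training refinement.
#'
#' Donor-level labels are noisy cell-level labels: a diseased donor's cells
#' are a mixture of normal and perturbed cells, so most T2D-donor cells are
#' not themselves disease-perturbed. The refinement addresses exactly this:
#' after an initial ND-vs-T2D fit, the positive training set is restricted
#' to T2D-donor cells scoring above the `refine_quantile` quantile of the
#' ND-donor cells' scores, and the model is refit; iterating concentrates
#' the positive class on genuinely perturbed cells. The final refit relaxes
#' the penalty by `refit_relax` since the refined labels are cleaner. Raw
#' model probabilities are the index (no rank re-normalization), so a fixed
#' threshold such as 0.89 is read on the probability scale.
#'
#' @param n_folds number of donor-grouped CV folds (>= 2; must not exceed
#'   the donor count of either endpoint state).
#' @param regularization_strength elastic-net penalty `lambda` (> 0,
#'   default 0.05). Strong regularization is deliberate: it limits
#'   overfitting to donor-specific expression signatures, which are
#'   perfectly label-predictive within the training donors but carry no
#'   disease information.
#' @param l1_ratio elastic-net mixing `alpha` in `[0, 1]` (default 0.5).
#' @param refine_rounds self-training refinement iterations (default 6;
#'   0 disables refinement).
#' @param refine_quantile ND-score quantile above which T2D-donor cells are
#'   kept as positives during refinement (default 0.95).
#' @param refit_relax multiplier on `lambda` for the final refit on refined
#'   labels (default 0.4).
#' @param seed RNG seed governing fold assignment.
#' @param use_hvg whether the model consumes HVGs (default) or all genes.
#' @param hvg_n number of HVGs when `use_hvg` (capped at the gene count).
#' @param norm_scale library-size scale factor for [normalize_log()].
#' @return an `IndexModelConfig` list.
#' @export
index_config <- function(n_folds = 5, regularization_strength = 0.05,
                         l1_ratio = 0.5, refine_rounds = 6,
                         refine_quantile = 0.95, refit_relax = 0.4,
                         seed = 1L, use_hvg = TRUE, hvg_n = 2000,
                         norm_scale = 1e4) {
  if (n_folds < 2) stop_value("n_folds must be >= 2")
  if (regularization_strength <= 0)
    stop_value("regularization_strength must be > 0")
  if (l1_ratio < 0 || l1_ratio > 1) stop_value("l1_ratio must be in [0,1]")
  if (refine_rounds < 0) stop_value("refine_rounds must be >= 0")
  if (refine_quantile <= 0 || refine_quantile >= 1)
    stop_value("refine_quantile must be in (0,1)")
  if (refit_relax <= 0) stop_value("refit_relax must be > 0")
  structure(list(n_folds = as.integer(n_folds),
                 regularization_strength = as.numeric(regularization_strength),
                 l1_ratio = as.numeric(l1_ratio),
                 refine_rounds = as.integer(refine_rounds),
                 refine_quantile = as.numeric(refine_quantile),
                 refit_relax = as.numeric(refit_relax),
                 seed = as.integer(seed),
                 use_hvg = isTRUE(use_hvg),
                 hvg_n = as.integer(hvg_n),
                 norm_scale = as.numeric(norm_scale)),
            class = "IndexModelConfig")
}

#' Assign donors of the endpoint states to cross-validation folds
#'
#' Stratified by state: ND donors and T2D donors are each split as evenly
#' as possible across folds (per-state fold sizes differ by at most one).
#' Donors of non-endpoint states receive no fold. Deterministic given
#' `seed`.
#'
#' @param cohort a [new_cohort()] object.
#' @param n_folds number of folds; each endpoint state needs >= `n_folds`
#'   donors.
#' @param seed RNG seed for the shuffle.
#' @return named integer vector mapping endpoint donor id -> fold (1-based).
#' @export
assign_donor_folds <- function(cohort, n_folds, seed = 1L) {
  donors <- cohort$donors
  fold <- integer(0)
  with_seed(seed, {
    for (st in c(0L, 2L)) {
      ids <- donors$donor_id[donors$state == st]
      if (length(ids) < n_folds)
        stop_value("state %s has %d donor(s) but %d folds were requested",
                   state_label(st), length(ids), n_folds)
      ids <- sample(ids)
      f <- rep_len(seq_len(n_folds), length(ids))
      fold[ids] <- f
    }
  })
  fold
}

# single penalized binomial fit with inverse-frequency class weights
.glmnet_binomial <- function(values, y, lambda, alpha) {
  w <- ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  glmnet::glmnet(values, y, family = "binomial", alpha = alpha,
                 lambda = lambda, weights = w, standardize = TRUE)
}

#' Fit the disease scorer on labeled training cells
#'
#' Fits the elastic-net binomial model, then (when `cfg$refine_rounds > 0`)
#' runs the self-training refinement described in [index_config()]. The
#' scorer maps a cell's expression vector to a probability-like value in
#' `[0, 1]`, higher = more T2D-like.
#'
#' @param train_matrix a `NormalizedMatrix` (cells x genes) of training
#'   cells.
#' @param cell_labels binary vector (0 = ND-donor cell, 1 = T2D-donor cell)
#'   aligned with the rows of `train_matrix`.
#' @param cfg an [index_config()].
#' @return an `index_model`; score cells with [predict_index()].
#' @export
fit_index_model <- function(train_matrix, cell_labels, cfg = index_config()) {
  y <- as.integer(cell_labels)
  if (length(unique(y)) < 2)
    stop_value("training cells contain a single class; need both ND and T2D cells")
  X <- train_matrix$values
  lam <- cfg$regularization_strength
  fit <- .glmnet_binomial(X, y, lam, cfg$l1_ratio)
  final_lam <- lam
  if (cfg$refine_rounds > 0) {
    s <- as.numeric(stats::predict(fit, X, type = "response", s = lam))
    neg <- which(y == 0)
    for (r in seq_len(cfg$refine_rounds)) {
      l <- if (r == cfg$refine_rounds) lam * cfg$refit_relax else lam
      thr <- stats::quantile(s[neg], cfg$refine_quantile)
      pos <- which(y == 1 & s > thr)
      if (length(pos) < 20) break      # refinement degenerated; keep last fit
      rows <- c(neg, pos)
      fit <- .glmnet_binomial(X[rows, , drop = FALSE],
                              c(rep(0L, length(neg)), rep(1L, length(pos))),
                              l, cfg$l1_ratio)
      final_lam <- l
      s <- as.numeric(stats::predict(fit, X, type = "response", s = l))
    }
  }
  structure(list(fit = fit, gene_ids = train_matrix$gene_ids,
                 lambda = final_lam),
            class = "index_model")
}

#' Score cells with a fitted index model
#'
#' @param model an [fit_index_model()] result.
#' @param norm a `NormalizedMatrix` over the model's gene set.
#' @return numeric vector of scores in `[0, 1]`, one per cell.
#' @export
predict_index <- function(model, norm) {
  if (!identical(norm$gene_ids, model$gene_ids))
    stop_integrity("gene set of the matrix to score differs from the model's")
  as.numeric(stats::predict(model$fit, norm$values, type = "response",
                            s = model$lambda))
}

#' Compute the per-cell pseudo disease-state index for one cell type
#'
#' Learns the ND-vs-T2D scorer under donor-grouped cross-validation and
#' scores every cell of the requested type exactly once: endpoint-state
#' cells receive out-of-fold scores (each cell is scored only by the model
#' whose training folds excluded its donor), and preT2D cells — never used
#' for training — receive the mean of all fold models' scores
#' (`fold = -1`), making their placement on the healthy-to-diseased
#' continuum a genuine prediction. The per-state mean index is expected to
#' increase monotonically along ND -> preT2D -> T2D when a disease program
#' is present.
#'
#' @param cohort a [new_cohort()] object (QC'd; see [qc_filter()]).
#' @param cell_type cell type to analyze.
#' @param cfg an [index_config()].
#' @return data.frame with columns `cell_id`, `cell_type`, `donor_id`,
#'   `state`, `index` (in `[0, 1]`), `fold` (held-out fold, or -1).
#' @export
compute_disease_index <- function(cohort, cell_type, cfg = index_config()) {
  sub <- subset_by_cell_type(cohort, cell_type)
  norm <- normalize_log(sub, scale = cfg$norm_scale)
  if (cfg$use_hvg && cfg$hvg_n < length(norm$gene_ids))
    norm <- select_hvg(norm, cfg$hvg_n)

  states <- cell_states(sub)
  folds <- tryCatch(
    assign_donor_folds(sub, cfg$n_folds, seed = cfg$seed),
    cellrisk_value_error = function(e)
      stop_value("cell type '%s': %s", cell_type, conditionMessage(e)))

  n <- nrow(norm$values)
  index <- rep(NA_real_, n)
  fold_of_cell <- rep(-1L, n)
  cell_fold <- folds[sub$cells$donor_id]          # NA for preT2D donors
  endpoint <- states %in% c(0L, 2L)
  mid <- !endpoint
  mid_scores <- matrix(NA_real_, nrow = sum(mid), ncol = cfg$n_folds)

  slice <- function(rows) {
    structure(list(values = norm$values[rows, , drop = FALSE],
                   gene_ids = norm$gene_ids,
                   cell_ids = norm$cell_ids[rows],
                   params = norm$params),
              class = "NormalizedMatrix")
  }
  for (k in seq_len(cfg$n_folds)) {
    train <- endpoint & !is.na(cell_fold) & cell_fold != k
    test <- endpoint & !is.na(cell_fold) & cell_fold == k
    model <- fit_index_model(slice(which(train)),
                             as.integer(states[train] == 2L), cfg)
    if (any(test)) {
      index[test] <- predict_index(model, slice(which(test)))
      fold_of_cell[test] <- k
    }
    if (any(mid)) mid_scores[, k] <- predict_index(model, slice(which(mid)))
  }
  if (any(mid)) index[mid] <- rowMeans(mid_scores)

  data.frame(cell_id = sub$cells$cell_id,
             cell_type = cell_type,
             donor_id = sub$cells$donor_id,
             state = states,
             index = index,
             fold = fold_of_cell,
             stringsAsFactors = FALSE)
}
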