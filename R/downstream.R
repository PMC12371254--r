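#' Aggregate raw counts into donor x compartment pseudobulk samples
#'
#' Sums raw counts per donor and risk compartment (risk / nonrisk). The
#' design is paired: both compartments of a donor are retained only when
#' both hold at least `min_cells` cells; other donors are excluded and
#' reported via a message.
#'
#' @param cohort a [new_cohort()] object.
#' @param risk a `RiskCall` data.frame covering the cohort's cells.
#' @param min_cells minimum cells per compartment (default 10).
#' @return a `PseudobulkMatrix`: list with `counts` (samples x genes dense
#'   matrix), `samples` (data.frame: `sample_id`, `donor_id`,
#'   `compartment`, `n_cells`) and `gene_ids`.
#' @export
pseudobulk_aggregate <- function(cohort, risk, min_cells = 10) {
  hit <- match(cohort$cells$cell_id, risk$cell_id)
  if (anyNA(hit))
    stop_integrity("risk labels do not cover the cohort: %d cell(s) missing",
                   sum(is.na(hit)))
  is_risk <- risk$is_risk[hit]
  donor <- cohort$cells$donor_id
  comp <- ifelse(is_risk, "risk", "nonrisk")
  grp <- paste(donor, comp, sep = "|")
  n_cells <- table(grp)
  keep_donor <- intersect(names(which(tapply(is_risk, donor, sum) >= min_cells)),
                          names(which(tapply(!is_risk, donor, sum) >= min_cells)))
  dropped <- setdiff(unique(donor), keep_donor)
  if (!length(keep_donor))
    stop_value("no donor has >= %d cells in both compartments; empty design",
               min_cells)
  if (length(dropped))
    message(sprintf("pseudobulk_aggregate: dropping %d donor(s) lacking %d cells in a compartment: %s",
                    length(dropped), min_cells, paste(dropped, collapse = ", ")))
  keep <- donor %in% keep_donor
  grp_f <- factor(grp[keep])
  # indicator^T %*% counts gives per-group column sums
  ind <- Matrix::sparseMatrix(i = as.integer(grp_f), j = which(keep),
                              x = 1, dims = c(nlevels(grp_f), nrow(cohort$counts)))
  pb <- as.matrix(ind %*% cohort$counts)
  rownames(pb) <- levels(grp_f)
  parts <- strsplit(levels(grp_f), "|", fixed = TRUE)
  samples <- data.frame(sample_id = levels(grp_f),
                        donor_id = vapply(parts, `[`, "", 1),
                        compartment = vapply(parts, `[`, "", 2),
                        n_cells = as.integer(n_cells[levels(grp_f)]),
                        stringsAsFactors = FALSE)
  structure(list(counts = pb, samples = samples,
                 gene_ids = colnames(cohort$counts)),
            class = "PseudobulkMatrix")
}

# median-of-ratios size factors (reference = geometric mean over samples,
# taken over genes expressed in every sample)
.size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- colMeans(lg)                      # log geometric mean per gene
  usable <- !is.na(ref) & apply(is.finite(lg), 2, all)
  if (!any(usable))
    stop_value("no gene is expressed in every pseudobulk sample; cannot compute size factors")
  sf <- apply(lg[, usable, drop = FALSE], 1, function(r)
    exp(stats::median(r - ref[usable])))
  sf / exp(mean(log(sf)))                  # normalize to geometric mean 1
}

#' Risk-vs-nonrisk pseudobulk differential expression
#'
#' A minimal negative-binomial Wald test: median-of-ratios size factors,
#' per-gene method-of-moments dispersion (Pearson residuals from a Poisson
#' fit of the donor + compartment log-linear model), then a negative
#' binomial GLM with donor and compartment terms and a Wald test on the
#' compartment (risk over nonrisk) coefficient, BH-adjusted across tested
#' genes. The donor term makes the design paired, since both compartments
#' come from the same donors. Genes with all-zero counts are skipped and
#' listed in the `skipped` attribute.
#'
#' @param pb a [pseudobulk_aggregate()] result with >= 2 complete donor
#'   pairs.
#' @return `DEResult` data.frame: `gene_id`, `log2fc` (risk over nonrisk),
#'   `p`, `p_adj`, `mean_risk`, `mean_nonrisk` (size-factor-normalized
#'   means), ordered as the input genes.
#' @export
de_test <- function(pb) {
  samples <- pb$samples
  donors_complete <- names(which(table(samples$donor_id) == 2))
  if (length(donors_complete) < 2)
    stop_value("need >= 2 donors with both compartments; have %d",
               length(donors_complete))
  keep <- samples$donor_id %in% donors_complete
  counts <- pb$counts[keep, , drop = FALSE]
  samples <- samples[keep, , drop = FALSE]
  sf <- .size_factors(counts)
  donor_f <- factor(samples$donor_id)
  comp_f <- factor(samples$compartment, levels = c("nonrisk", "risk"))
  off <- log(sf)
  norm <- counts / sf

  genes <- pb$gene_ids
  out <- data.frame(gene_id = genes, log2fc = NA_real_, p = NA_real_,
                    mean_risk = NA_real_, mean_nonrisk = NA_real_,
                    stringsAsFactors = FALSE)
  skipped <- character(0)
  X <- stats::model.matrix(~ donor_f + comp_f)
  comp_col <- ncol(X)
  for (g in seq_along(genes)) {
    yg <- counts[, g]
    out$mean_risk[g] <- mean(norm[comp_f == "risk", g])
    out$mean_nonrisk[g] <- mean(norm[comp_f == "nonrisk", g])
    if (all(yg == 0)) { skipped <- c(skipped, genes[g]); next }
    pois <- suppressWarnings(
      stats::glm.fit(X, yg, family = stats::poisson(), offset = off))
    mu <- pois$fitted.values
    df_resid <- length(yg) - ncol(X)
    alpha <- if (df_resid > 0)
      max(0, sum((yg - mu)^2 - mu) / sum(mu^2)) else 0
    fam <- if (alpha > 1e-8) MASS::negative.binomial(theta = 1 / alpha)
           else stats::poisson()
    fit <- suppressWarnings(stats::glm.fit(X, yg, family = fam, offset = off))
    cf <- fit$coefficients[comp_col]
    # Wald SE from the weighted least-squares covariance
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- try(solve(XtWX), silent = TRUE)
    if (inherits(cov, "try-error") || is.na(cf)) {
      skipped <- c(skipped, genes[g]); next
    }
    se <- sqrt(cov[comp_col, comp_col])
    z <- if (se > 0) cf / se else 0
    out$log2fc[g] <- cf / log(2)
    out$p[g] <- 2 * stats::pnorm(-abs(z))
  }
  tested <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[tested] <- bh_adjust(out$p[tested])
  attr(out, "skipped") <- skipped
  out
}

#' Louvain subtype clustering of cells
#'
#' Standard PCA -> kNN graph -> Louvain community detection. Cluster ids
#' are reassigned in decreasing order of cluster size, so cluster 1 is the
#' largest. Deterministic given `seed`.
#'
#' @param norm a `NormalizedMatrix` (see [normalize_log()]).
#' @param n_neighbors neighbors in the kNN graph (default 15).
#' @param n_pcs number of principal components (default 30; capped at the
#'   data's rank).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed.
#' @return integer cluster labels (1-based), named by cell id.
#' @export
subtype_cluster <- function(norm, n_neighbors = 15, n_pcs = 30,
                            resolution = 1, seed = 1L) {
  n <- nrow(norm$values)
  if (n < n_neighbors + 1)
    stop_value("need at least n_neighbors + 1 = %d cells; have %d",
               n_neighbors + 1, n)
  x <- as.matrix(norm$values)
  n_pcs <- min(n_pcs, n - 1, ncol(x))
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  d2 <- as.matrix(stats::dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[2:(n_neighbors + 1)]
    cbind(i, nb)
  }))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(memb)])
  names(labels) <- norm$cell_ids
  labels
}

#' Risk-cell aggregation dynamics across subtypes and disease stages
#'
#' For every (cluster, stage) pair reports cell counts, risk-cell counts
#' and fractions, plus a hypergeometric enrichment test of risk cells in
#' the cluster relative to the stage's overall risk pool, BH-adjusted
#' across clusters within each stage. Shows where risk cells aggregate as
#' disease progresses.
#'
#' @param clusters labels from [subtype_cluster()] (named by cell id).
#' @param risk a `RiskCall` data.frame over the same cells.
#' @param cohort the cohort (supplies donor states).
#' @return `SubtypeDynamics` data.frame: `cluster`, `state`, `n_cells`,
#'   `n_risk`, `risk_fraction`, `p`, `p_adj`.
#' @export
risk_aggregation_dynamics <- function(clusters, risk, cohort) {
  ids <- names(clusters)
  if (is.null(ids) || !setequal(ids, risk$cell_id))
    stop_integrity("cluster labels and risk calls must cover the same cells")
  risk_of <- stats::setNames(risk$is_risk, risk$cell_id)[ids]
  state_of <- cell_states(cohort)[match(ids, cohort$cells$cell_id)]
  if (anyNA(state_of))
    stop_integrity("cluster labels reference cells absent from the cohort")
  out <- expand.grid(cluster = sort(unique(as.integer(clusters))),
                     state = sort(unique(state_of)),
                     KEEP.OUT.ATTRS = FALSE)
  out$n_cells <- 0L; out$n_risk <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- clusters == out$cluster[i] & state_of == out$state[i]
    out$n_cells[i] <- sum(sel)
    out$n_risk[i] <- sum(risk_of[sel])
  }
  out$risk_fraction <- ifelse(out$n_cells > 0, out$n_risk / out$n_cells, 0)
  out$p <- NA_real_
  for (st in unique(out$state)) {
    rows <- which(out$state == st)
    m <- sum(out$n_risk[rows])                 # risk cells in the stage
    nn <- sum(out$n_cells[rows]) - m           # nonrisk cells in the stage
    out$p[rows] <- stats::phyper(out$n_risk[rows] - 1L, m, nn,
                                 out$n_cells[rows], lower.tail = FALSE)
    out$p[rows][out$n_cells[rows] == 0] <- 1
    out$p_adj[rows] <- bh_adjust(out$p[rows])
  }
  class(out) <- c("SubtypeDynamics", "data.frame")
  out
}
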