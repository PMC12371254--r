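#' Quality-control filter on detected genes and cells
#'
#' Removes cells detecting fewer than `min_genes_per_cell` genes, then genes
#' detected in fewer than `min_cells_per_gene` of the surviving cells — in
#' that order, so the gene filter sees post-cell-filter detection counts.
#'
#' @param cohort a [new_cohort()] object (assumed doublet-free; doublet
#'   removal is upstream of this package).
#' @param min_genes_per_cell minimum number of genes with count > 0 a cell
#'   must detect (default 200).
#' @param min_cells_per_gene minimum number of retained cells a gene must be
#'   detected in (default 3).
#' @return the filtered `Cohort`.
#' @export
qc_filter <- function(cohort, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    stop_value("QC thresholds must be >= 0")
  detected <- cohort$counts > 0
  keep_cells <- Matrix::rowSums(detected) >= min_genes_per_cell
  if (!any(keep_cells))
    stop_value("qc_filter removed every cell (min_genes_per_cell = %d)",
               min_genes_per_cell)
  counts <- cohort$counts[keep_cells, , drop = FALSE]
  keep_genes <- Matrix::colSums(counts > 0) >= min_cells_per_gene
  counts <- counts[, keep_genes, drop = FALSE]
  cells <- cohort$cells[keep_cells, , drop = FALSE]
  rownames(cells) <- NULL
  donors <- cohort$donors[cohort$donors$donor_id %in% cells$donor_id, ,
                          drop = FALSE]
  rownames(donors) <- NULL
  structure(list(counts = counts, cells = cells, donors = donors),
            class = "Cohort")
}

#' Library-size log-normalization
#'
#' `value[c, g] = ln(1 + scale * count[c, g] / total[c])`, with `total[c]`
#' the cell's summed counts over the full gene set, computed before any
#' feature selection so HVG choice cannot change library-size scaling.
#'
#' @param cohort a [new_cohort()] object with no zero-count cells (run
#'   [qc_filter()] with `min_genes_per_cell >= 1` first).
#' @param scale library-size scale factor (default `1e4`).
#' @return a `NormalizedMatrix`: list with `values` (sparse cells x genes),
#'   `gene_ids`, `cell_ids`, and a `params` record.
#' @export
normalize_log <- function(cohort, scale = 1e4) {
  totals <- Matrix::rowSums(cohort$counts)
  if (any(totals == 0))
    stop_value("%d cell(s) have zero total counts; run qc_filter first",
               sum(totals == 0))
  v <- cohort$counts
  # operate on the sparse slots directly: zeros stay zero under log1p
  vt <- methods::as(methods::as(v, "TsparseMatrix"), "generalMatrix")
  vt@x <- log1p(scale * vt@x / totals[vt@i + 1L])
  structure(list(values = methods::as(vt, "CsparseMatrix"),
                 gene_ids = colnames(cohort$counts),
                 cell_ids = cohort$cells$cell_id,
                 params = list(scale = scale, log_base = exp(1),
                               hvg_n = NA_integer_)),
            class = "NormalizedMatrix")
}

#' Select highly variable genes by variance of normalized expression
#'
#' Retains the `n_top` genes with the highest sample variance of
#' log-normalized values; exact ties are broken by gene id in lexicographic
#' order, so the selection is deterministic and invariant to input gene
#' order. Retained genes keep their original column order.
#'
#' @param norm a [normalize_log()] result.
#' @param n_top number of genes to retain (1..number of genes).
#' @return a `NormalizedMatrix` restricted to the selected genes.
#' @export
select_hvg <- function(norm, n_top = 2000) {
  g <- length(norm$gene_ids)
  if (n_top < 1 || n_top > g)
    stop_value("n_top must be in [1, %d]; got %s", g, format(n_top))
  v <- norm$values
  n <- nrow(v)
  mu <- Matrix::colMeans(v)
  m2 <- Matrix::colMeans(v^2)
  vars <- (m2 - mu^2) * n / max(1, n - 1)
  ord <- order(-vars, norm$gene_ids)
  keep <- sort(ord[seq_len(n_top)])
  structure(list(values = v[, keep, drop = FALSE],
                 gene_ids = norm$gene_ids[keep],
                 cell_ids = norm$cell_ids,
                 params = utils::modifyList(norm$params, list(hvg_n = as.integer(n_top)))),
            class = "NormalizedMatrix")
}
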