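#' Multi-donor single-cell cohort container
#'
#' A `Cohort` bundles a sparse cells x genes raw count matrix with a cell
#' table (cell id, donor id, cell type) and a donor table (donor id, ordinal
#' disease state, optional clinical covariates). Cells are rows and genes are
#' columns everywhere in this package.
#'
#' Disease states are coded ordinally: ND = 0, preT2D = 1, T2D = 2.
#' Missing covariates are carried as `NA` and propagated; association
#' functions drop incomplete pairs and report the n actually used.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells x genes.
#' @param cells data.frame with columns `cell_id`, `donor_id`, `cell_type`.
#' @param donors data.frame with columns `donor_id`, `state` (integer 0/1/2
#'   or one of `"ND"`, `"preT2D"`, `"T2D"`), plus optional covariate columns
#'   (e.g. `hba1c`, `bmi`, `c_peptide`, `age`, `sex`).
#'
#' @return An object of class `Cohort`: a list with elements `counts`
#'   (`dgCMatrix`, dimnames set to cell/gene ids), `cells` and `donors`.
#' @export
new_cohort <- function(counts, cells, donors) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  donors <- as.data.frame(donors, stringsAsFactors = FALSE)
  need_cell <- c("cell_id", "donor_id", "cell_type")
  miss <- setdiff(need_cell, names(cells))
  if (length(miss))
    stop_schema("cell table is missing column(s): %s", paste(miss, collapse = ", "))
  need_donor <- c("donor_id", "state")
  miss <- setdiff(need_donor, names(donors))
  if (length(miss))
    stop_schema("donor table is missing column(s): %s", paste(miss, collapse = ", "))
  donors$state <- map_state(donors$state)
  rownames(counts) <- cells$cell_id
  if (is.null(colnames(counts)))
    stop_schema("counts matrix must carry gene ids as column names")
  obj <- structure(list(counts = counts, cells = cells, donors = donors),
                   class = "Cohort")
  validate_cohort(obj)
}

#' Validate a Cohort's structural invariants
#'
#' Checks non-negative integer counts, matching dimensions, unique cell and
#' gene ids, and referential integrity between the cell and donor tables
#' (every cell maps to a known donor; every donor owns at least one cell).
#'
#' @param cohort a [new_cohort()] object.
#' @return `cohort`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  counts <- cohort$counts
  cells <- cohort$cells
  donors <- cohort$donors
  if (nrow(counts) != nrow(cells))
    stop_schema("counts has %d rows but the cell table has %d rows",
                nrow(counts), nrow(cells))
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop_value("counts must be non-negative integers")
  if (anyDuplicated(cells$cell_id))
    stop_value("duplicated cell ids: %s",
               paste(unique(cells$cell_id[duplicated(cells$cell_id)]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_value("duplicated gene ids")
  if (anyDuplicated(donors$donor_id))
    stop_value("duplicated donor ids")
  unknown <- setdiff(cells$donor_id, donors$donor_id)
  if (length(unknown))
    stop_integrity("cells reference donor(s) absent from the donor table: %s",
                   paste(unknown, collapse = ", "))
  orphan <- setdiff(donors$donor_id, cells$donor_id)
  if (length(orphan))
    stop_integrity("donor(s) own no cells: %s", paste(orphan, collapse = ", "))
  if (!all(cohort$donors$state %in% STATE_LEVELS))
    stop_value("donor states must be coded 0 (ND), 1 (preT2D), 2 (T2D)")
  cohort
}

# Map disease-state labels to ordinal codes {0,1,2}. Unknown strings are
# rejected unless listed in `aliases` (name = accepted string, value = one of
# "ND","preT2D","T2D").
map_state <- function(state, aliases = NULL) {
  if (is.numeric(state)) {
    s <- as.integer(state)
    if (!all(s %in% STATE_LEVELS))
      stop_value("numeric donor states must be in {0,1,2}; got: %s",
                 paste(unique(s[!s %in% STATE_LEVELS]), collapse = ", "))
    return(s)
  }
  s <- as.character(state)
  if (!is.null(aliases)) {
    hit <- s %in% names(aliases)
    s[hit] <- unname(aliases[s[hit]])
  }
  bad <- setdiff(unique(s), names(STATE_LEVELS))
  if (length(bad))
    stop_value("unrecognised disease state(s): %s (accepted: %s)",
               paste(bad, collapse = ", "),
               paste(names(STATE_LEVELS), collapse = ", "))
  unname(STATE_LEVELS[s])
}

#' Load a cohort from Matrix Market counts plus TSV sidecar tables
#'
#' Reads `matrix.mtx` (sparse counts), `cells.tsv` (`cell_id`, `donor_id`,
#' `cell_type`), `genes.tsv` (`gene_id`) and `donors.tsv` (`donor_id`,
#' `state`, optional covariates). The count matrix may be stored either as
#' cells x genes or transposed (genes x cells, the 10x convention); the
#' orientation is detected from the dimensions declared in the sidecar
#' tables and the matrix is returned as cells x genes.
#'
#' @param dir directory holding `matrix.mtx`, `cells.tsv`, `genes.tsv`,
#'   `donors.tsv`. Alternatively pass the four paths explicitly.
#' @param counts_path,cells_path,genes_path,donors_path explicit file paths,
#'   overriding `dir`.
#' @param state_aliases optional named character vector extending accepted
#'   disease-state strings, e.g. `c("Non-diabetic" = "ND")`.
#' @return a validated [new_cohort()] object.
#' @export
load_cohort <- function(dir = NULL,
                        counts_path = file.path(dir, "matrix.mtx"),
                        cells_path = file.path(dir, "cells.tsv"),
                        genes_path = file.path(dir, "genes.tsv"),
                        donors_path = file.path(dir, "donors.tsv"),
                        state_aliases = NULL) {
  for (p in c(counts_path, cells_path, genes_path, donors_path))
    if (!file.exists(p)) stop_value("input file not found: %s", p)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("cell_id", "donor_id", "cell_type")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop_schema("%s is missing column(s): %s", cells_path,
                paste(miss, collapse = ", "))
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!"gene_id" %in% names(genes))
    stop_schema("%s is missing column: gene_id", genes_path)
  donors <- utils::read.delim(donors_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("donor_id", "state"), names(donors))
  if (length(miss))
    stop_schema("%s is missing column(s): %s", donors_path,
                paste(miss, collapse = ", "))
  donors$donor_id <- as.character(donors$donor_id)
  donors$state <- map_state(donors$state, aliases = state_aliases)

  m <- Matrix::readMM(counts_path)
  nc <- nrow(cells); ng <- nrow(genes)
  if (nrow(m) == nc && ncol(m) == ng) {
    # already cells x genes
  } else if (nrow(m) == ng && ncol(m) == nc) {
    m <- Matrix::t(m)
  } else {
    stop_schema("matrix dimensions %d x %d match neither %d cells x %d genes nor its transpose",
                nrow(m), ncol(m), nc, ng)
  }
  colnames(m) <- genes$gene_id
  new_cohort(m, cells, donors)
}

#' Write a cohort (and optional simulation truth) to plain-text files
#'
#' Emits `matrix.mtx` (cells x genes), `cells.tsv`, `genes.tsv`,
#' `donors.tsv`, and, when `truth` is supplied, `truth.tsv`. The files
#' round-trip exactly through [load_cohort()], and repeated writes of the
#' same cohort are byte-identical.
#'
#' @param cohort a [new_cohort()] object.
#' @param dir output directory (created if absent).
#' @param truth optional `SimTruth` from [simulate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- try(Matrix::writeMM(cohort$counts, file.path(dir, "matrix.mtx")),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_value("failed writing %s: %s", file.path(dir, "matrix.mtx"),
               attr(ok, "condition")$message)
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv(cohort$cells, file.path(dir, "cells.tsv"))
  write_tsv(data.frame(gene_id = colnames(cohort$counts)),
            file.path(dir, "genes.tsv"))
  donors <- cohort$donors
  donors$state <- state_label(donors$state)
  write_tsv(donors, file.path(dir, "donors.tsv"))
  if (!is.null(truth))
    write_tsv(truth$cells, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Restrict a cohort to one cell type
#'
#' Keeps exactly the cells of `cell_type`; the donor table is restricted to
#' donors retaining at least one cell, and the gene set is unchanged.
#' Subsetting is idempotent.
#'
#' @param cohort a [new_cohort()] object.
#' @param cell_type a cell-type label present in the cohort.
#' @return a `Cohort` containing only cells of the requested type.
#' @export
subset_by_cell_type <- function(cohort, cell_type) {
  types <- unique(cohort$cells$cell_type)
  if (!cell_type %in% types)
    stop_value("unknown cell type '%s'; available: %s", cell_type,
               paste(sort(types), collapse = ", "))
  keep <- cohort$cells$cell_type == cell_type
  cells <- cohort$cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  donors <- cohort$donors[cohort$donors$donor_id %in% cells$donor_id, ,
                          drop = FALSE]
  rownames(donors) <- NULL
  structure(list(counts = cohort$counts[keep, , drop = FALSE],
                 cells = cells, donors = donors),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  st <- table(factor(x$donors$state, levels = STATE_LEVELS,
                     labels = names(STATE_LEVELS)))
  cat(sprintf("Cohort: %d cells x %d genes, %d donors (%s)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$donors),
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  cat(sprintf("cell types: %s\n",
              paste(sort(unique(x$cells$cell_type)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.Cohort <- function(x) dim(x$counts)

# donor state of each cell, as an integer vector aligned with the cell table
cell_states <- function(cohort) {
  cohort$donors$state[match(cohort$cells$donor_id, cohort$donors$donor_id)]
}
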