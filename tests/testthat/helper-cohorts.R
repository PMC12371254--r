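# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read.

# hand-built 3-cell x 2-gene cohort over 2 donors
tiny_cohort <- function() {
  counts <- Matrix::Matrix(matrix(c(1, 0,
                                    2, 1,
                                    0, 3), nrow = 3, byrow = TRUE,
                                  dimnames = list(NULL, c("gA", "gB"))),
                           sparse = TRUE)
  cells <- data.frame(cell_id = c("c1", "c2", "c3"),
                      donor_id = c("d1", "d1", "d2"),
                      cell_type = c("beta", "beta", "alpha"))
  donors <- data.frame(donor_id = c("d1", "d2"), state = c("ND", "T2D"))
  new_cohort(counts, cells, donors)
}

# random multi-donor cohort with uniform counts (no disease structure)
rand_cohort <- function(n_cells = 50, n_genes = 30, n_donors = 4, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, lambda = 1), nrow = n_cells,
                   dimnames = list(NULL, sprintf("g%03d", seq_len(n_genes))))
  donors <- sprintf("d%02d", seq_len(n_donors))
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                      donor_id = rep_len(donors, n_cells),
                      cell_type = "beta")
  dt <- data.frame(donor_id = donors,
                   state = rep_len(c(0L, 1L, 2L), n_donors))
  new_cohort(Matrix::Matrix(counts, sparse = TRUE), cells, dt)
}

# scaled-down simulated cohort for fast model tests
small_sim <- function(seed = 1, ...) {
  simulate_cohort(sim_config(n_donors = c(5, 5, 5), cells_per_donor = 100,
                             n_genes = 300, n_perturbed_genes = 40,
                             seed = seed, ...))
}

# small index configuration matched to small_sim
small_index_cfg <- function(seed = 1, ...) {
  index_config(n_folds = 3, seed = seed, ...)
}

# NormalizedMatrix built directly from a dense matrix
as_norm <- function(m, cell_ids = sprintf("c%04d", seq_len(nrow(m))),
                    gene_ids = colnames(m)) {
  structure(list(values = Matrix::Matrix(m, sparse = TRUE),
                 gene_ids = gene_ids, cell_ids = cell_ids,
                 params = list(scale = NA, log_base = exp(1), hvg_n = NA)),
            class = "NormalizedMatrix")
}
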