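truth_risk <- function(sim) {
  data.frame(cell_id = sim$truth$cells$cell_id,
             is_risk = sim$truth$cells$is_risk_true,
             threshold = NA_real_, method = "truth", cell_type = "beta",
             stringsAsFactors = FALSE)
}

test_that("pseudobulk sums per donor and compartment are exact", {
  counts <- Matrix::Matrix(matrix(c(1, 0,
                                    2, 1,
                                    0, 0), nrow = 3, byrow = TRUE,
                                  dimnames = list(NULL, c("gA", "gB"))),
                           sparse = TRUE)
  cells <- data.frame(cell_id = c("c1", "c2", "c3"), donor_id = "d1",
                      cell_type = "beta")
  donors <- data.frame(donor_id = "d1", state = 2L)
  co <- new_cohort(counts, cells, donors)
  risk <- data.frame(cell_id = cells$cell_id, is_risk = TRUE,
                     threshold = 0, method = "fixed", cell_type = "beta")
  pb <- pseudobulk_aggregate(co, risk, min_cells = 0)
  expect_equal(unname(pb$counts["d1|risk", ]), c(3, 1))

  # all nonrisk with min_cells = 1 leaves no paired donor
  none <- risk; none$is_risk <- FALSE
  expect_error(pseudobulk_aggregate(co, none, min_cells = 1),
               class = "cellrisk_value_error")
})

test_that("pseudobulk matches brute-force group sums and conserves counts", {
  sim <- small_sim(seed = 3)
  risk <- truth_risk(sim)
  pb <- suppressMessages(pseudobulk_aggregate(sim$cohort, risk, min_cells = 5))
  m <- as.matrix(sim$cohort$counts)
  for (i in sample(nrow(pb$samples), 4)) {
    s <- pb$samples[i, ]
    rows <- sim$cohort$cells$donor_id == s$donor_id &
      (risk$is_risk == (s$compartment == "risk"))
    expect_equal(unname(pb$counts[s$sample_id, ]), unname(colSums(m[rows, ])))
    expect_equal(s$n_cells, sum(rows))
  }
  kept <- sim$cohort$cells$donor_id %in% pb$samples$donor_id
  expect_equal(sum(pb$counts), sum(m[kept, ]))
})

test_that("identical samples give zero fold-change and p = 1", {
  counts <- matrix(rep(c(5, 9, 2), each = 8), nrow = 8,
                   dimnames = list(NULL, c("g1", "g2", "g3")))
  samples <- data.frame(sample_id = sprintf("s%d", 1:8),
                        donor_id = rep(sprintf("d%d", 1:4), each = 2),
                        compartment = rep(c("nonrisk", "risk"), 4),
                        n_cells = 10L)
  rownames(counts) <- samples$sample_id
  pb <- structure(list(counts = counts, samples = samples,
                       gene_ids = colnames(counts)),
                  class = "PseudobulkMatrix")
  de <- de_test(pb)
  expect_equal(de$log2fc, rep(0, 3), tolerance = 1e-8)
  expect_equal(de$p, rep(1, 3), tolerance = 1e-8)
  expect_error(de_test(structure(list(counts = counts[1:2, ],
                                      samples = samples[1:2, ],
                                      gene_ids = colnames(counts)),
                                 class = "PseudobulkMatrix")),
               class = "cellrisk_value_error")
})

test_that("all-zero genes are skipped and reported", {
  sim <- small_sim(seed = 5)
  m <- as.matrix(sim$cohort$counts)
  m[, 1] <- 0
  co <- new_cohort(Matrix::Matrix(m, sparse = TRUE), sim$cohort$cells,
                   sim$cohort$donors)
  pb <- suppressMessages(pseudobulk_aggregate(co, truth_risk(sim), min_cells = 5))
  de <- de_test(pb)
  expect_true(colnames(m)[1] %in% attr(de, "skipped"))
  expect_true(is.na(de$p[de$gene_id == colnames(m)[1]]))
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})

test_that("two separated blobs are recovered as two clusters", {
  skip_if_not_installed("mclust")
  set.seed(3)
  n <- 100
  blob <- rbind(matrix(rnorm(n * 20, mean = 0), ncol = 20),
                matrix(rnorm(n * 20, mean = 4), ncol = 20))
  nm <- as_norm(abs(blob), gene_ids = sprintf("g%02d", 1:20))
  labels <- subtype_cluster(nm, n_neighbors = 10, n_pcs = 5,
                            resolution = 0.2, seed = 3)
  expect_equal(length(unique(labels)), 2L)
  expect_equal(mclust::adjustedRandIndex(labels, rep(1:2, each = n)), 1.0)
  # determinism
  labels2 <- subtype_cluster(nm, n_neighbors = 10, n_pcs = 5,
                             resolution = 0.2, seed = 3)
  expect_identical(labels, labels2)
  # cluster ids ordered by size descending
  expect_true(all(diff(as.integer(table(labels))) <= 0))
})

test_that("vanishing resolution collapses a connected graph to one cluster", {
  set.seed(6)
  nm <- as_norm(matrix(abs(rnorm(60 * 10)), 60, 10),
                gene_ids = sprintf("g%02d", 1:10))
  labels <- subtype_cluster(nm, n_neighbors = 10, n_pcs = 5,
                            resolution = 1e-4, seed = 1)
  expect_equal(length(unique(labels)), 1L)
  expect_error(subtype_cluster(as_norm(matrix(1, 5, 3,
                                              dimnames = list(NULL, c("a", "b", "c")))),
                               n_neighbors = 10),
               class = "cellrisk_value_error")
})

test_that("risk aggregation dynamics: degenerate and extremal cases", {
  sim <- small_sim(seed = 9)
  cells <- sim$cohort$cells$cell_id
  clusters <- setNames(rep(1:3, length.out = length(cells)), cells)
  none <- truth_risk(sim); none$is_risk <- FALSE
  dyn <- risk_aggregation_dynamics(clusters, none, sim$cohort)
  expect_true(all(dyn$risk_fraction == 0))
  expect_true(all(dyn$p == 1))

  # put every risk cell of every stage into cluster 1
  risk <- truth_risk(sim)
  clusters[] <- ifelse(risk$is_risk[match(names(clusters), risk$cell_id)], 1L,
                       rep(2:3, length.out = length(cells)))
  dyn <- risk_aggregation_dynamics(clusters, risk, sim$cohort)
  for (st in unique(dyn$state)) {
    rows <- dyn[dyn$state == st, ]
    expect_equal(rows$cluster[which.min(rows$p)], 1)
  }
  bad <- clusters[-1]
  expect_error(risk_aggregation_dynamics(bad, risk, sim$cohort),
               class = "cellrisk_integrity_error")
})

test_that("stage risk proportions equal size-weighted cluster fractions", {
  sim <- small_sim(seed = 11)
  cells <- sim$cohort$cells$cell_id
  set.seed(1)
  clusters <- setNames(sample(1:4, length(cells), replace = TRUE), cells)
  risk <- truth_risk(sim)
  dyn <- risk_aggregation_dynamics(clusters, risk, sim$cohort)
  st_of <- cell_states <- sim$cohort$donors$state[
    match(sim$cohort$cells$donor_id, sim$cohort$donors$donor_id)]
  for (st in unique(dyn$state)) {
    rows <- dyn[dyn$state == st, ]
    expect_equal(sum(rows$n_cells * rows$risk_fraction) / sum(rows$n_cells),
                 mean(risk$is_risk[st_of == st]))
  }
})

test_that("a cluster with an elevated risk rate is flagged by the enrichment test", {
  set.seed(33)
  hits <- replicate(100, {
    n <- 1200
    clusters <- sample(1:4, n, replace = TRUE)
    base <- 0.08
    p <- ifelse(clusters == 1, 3 * base, base)
    is_risk <- rbinom(n, 1, p) == 1
    ids <- sprintf("c%04d", seq_len(n))
    cells <- data.frame(cell_id = ids, donor_id = "d1", cell_type = "beta")
    donors <- data.frame(donor_id = "d1", state = 2L)
    co <- new_cohort(Matrix::Matrix(matrix(1L, n, 1, dimnames = list(NULL, "g")),
                                    sparse = TRUE), cells, donors)
    risk <- data.frame(cell_id = ids, is_risk = is_risk, threshold = NA,
                       method = "truth", cell_type = "beta")
    dyn <- risk_aggregation_dynamics(setNames(clusters, ids), risk, co)
    dyn$p_adj[dyn$cluster == 1] < 0.05 && all(dyn$p_adj[dyn$cluster != 1] >= 0.05)
  })
  expect_gte(mean(hits), 0.95)
})
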