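#' Run the full risk-cell workflow from a configuration
#'
#' Orchestrates: simulate (optional) -> QC/normalize -> disease index ->
#' risk calling -> staging/association -> pseudobulk DE -> subtype
#' dynamics, writing each stage's outputs as TSV/JSON under `out_dir`
#' together with a run manifest (`manifest.json`) recording the package
#' version, the configuration snapshot, input checksums, seeds and output
#' paths. Any stage except the cohort source can be skipped via the
#' config. Reruns with an identical configuration produce byte-identical
#' stage outputs; the manifest additionally carries a wall-clock timestamp
#' and output checksums as provenance.
#'
#' Configuration (YAML file or R list). Top level: `out_dir`, `seed`,
#' `cell_type`. Either `simulate:` (fields of [sim_config()]) or
#' `cohort: {dir: ...}`. Optional blocks: `qc` (`min_genes_per_cell`,
#' `min_cells_per_gene`), `index` (fields of [index_config()]), `call`
#' (`method`: fixed|quantile|sliding_window, `threshold`, `q`, `grid`,
#' `min_risk_fraction`), `stage` (`cut_low`, `cut_high`, `n_boot`),
#' `associate` (`covariates`: character vector), `de` (`min_cells`),
#' `dynamics` (`n_neighbors`, `n_pcs`, `resolution`). A block set to
#' `FALSE` (or, for `de`/`dynamics`/`associate`, left absent) is skipped.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return the output directory, invisibly; stage results are also
#'   returned as the attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop_value("no output directory: set out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  cell_type <- cfg$cell_type %||% "beta"
  manifest <- list(tool = "cellrisk",
                   version = as.character(utils::packageVersion("cellrisk")),
                   config = cfg, seed = seed, stages = list(),
                   started = format(Sys.time(), tz = "UTC"))
  outputs <- character(0)
  fail <- function(stage, e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop_value("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  emit_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }
  block <- function(name, default = list()) {
    b <- cfg[[name]]
    if (isFALSE(b)) return(NULL)
    b %||% default
  }
  on <- function(name) !is.null(block(name, NULL)) || !is.null(cfg[[name]])

  # --- cohort source -------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulate) && !isFALSE(cfg$simulate)) {
    sc <- cfg$simulate
    if (isTRUE(sc)) sc <- list()
    sc$seed <- sc$seed %||% seed
    sim <- tryCatch(simulate_cohort(do.call(sim_config, sc)),
                    error = function(e) fail("simulate", e))
    cohort <- sim$cohort
    truth <- sim$truth
    cdir <- file.path(out_dir, "cohort")
    write_cohort(cohort, cdir, truth = truth)
    outputs <- c(outputs, list.files(cdir, full.names = TRUE))
    manifest$stages$simulate <- list(dir = cdir,
                                     n_cells = nrow(cohort$counts),
                                     n_donors = nrow(cohort$donors))
  } else if (!is.null(cfg$cohort$dir)) {
    cohort <- tryCatch(load_cohort(cfg$cohort$dir),
                       error = function(e) fail("load", e))
    manifest$input_checksums <- as.list(tools::md5sum(
      list.files(cfg$cohort$dir, full.names = TRUE)))
    manifest$stages$load <- list(dir = cfg$cohort$dir,
                                 n_cells = nrow(cohort$counts),
                                 n_donors = nrow(cohort$donors))
  } else stop_value("config must provide either a 'simulate' block or cohort$dir")
  message(sprintf("cohort: %d cells, %d donors", nrow(cohort$counts),
                  nrow(cohort$donors)))

  # --- qc ------------------------------------------------------------------
  qc <- block("qc", list(min_genes_per_cell = 1, min_cells_per_gene = 0))
  if (!is.null(qc)) {
    before <- nrow(cohort$counts)
    cohort <- tryCatch(
      qc_filter(cohort, qc$min_genes_per_cell %||% 1,
                qc$min_cells_per_gene %||% 0),
      error = function(e) fail("qc", e))
    message(sprintf("qc: %d -> %d cells, %d genes retained", before,
                    nrow(cohort$counts), ncol(cohort$counts)))
    manifest$stages$qc <- list(cells_in = before,
                               cells_out = nrow(cohort$counts),
                               genes_out = ncol(cohort$counts))
  }

  # --- disease index -------------------------------------------------------
  icfg_args <- block("index")
  icfg_args$seed <- icfg_args$seed %||% seed
  icfg <- do.call(index_config, icfg_args)
  indexes <- tryCatch(compute_disease_index(cohort, cell_type, icfg),
                      error = function(e) fail("index", e))
  emit_tsv(indexes[, c("cell_id", "cell_type", "index", "fold")], "index.tsv")
  manifest$stages$index <- list(n_cells = nrow(indexes),
                                n_folds = icfg$n_folds, path = "index.tsv")
  message(sprintf("index: scored %d %s cells", nrow(indexes), cell_type))

  # --- risk calling --------------------------------------------------------
  cb <- block("call", list(method = "sliding_window"))
  method <- cb$method %||% "sliding_window"
  risk <- switch(method,
    fixed = call_risk_fixed(indexes, cb$threshold %||% 0.89),
    quantile = call_risk_quantile(indexes, cb$q %||% 0.9),
    sliding_window = {
      sw <- tryCatch(call_risk_sliding_window(
        indexes, cohort,
        grid = cb$grid %||% seq(0.05, 0.95, by = 0.05),
        min_risk_fraction = cb$min_risk_fraction %||% 0.01),
        error = function(e) fail("call", e))
      emit_tsv(sw$trace, "threshold_trace.tsv")
      sw$risk
    },
    stop_value("unknown risk-calling method '%s'", method))
  emit_tsv(risk, "risk.tsv")
  manifest$stages$call <- list(method = method,
                               threshold = risk$threshold[1],
                               n_risk = sum(risk$is_risk), path = "risk.tsv")
  message(sprintf("call: %d/%d risk cells at threshold %.3f (%s)",
                  sum(risk$is_risk), nrow(risk), risk$threshold[1], method))

  # --- staging -------------------------------------------------------------
  results <- list(indexes = indexes, risk = risk, truth = truth)
  sb <- block("stage", list())
  if (!is.null(sb)) {
    profiles <- tryCatch(donor_risk_proportions(risk, cohort),
                         error = function(e) fail("stage", e))
    profiles$predicted_state <- stage_by_rule(profiles$proportion,
                                              sb$cut_low %||% 0.10,
                                              sb$cut_high %||% 0.20)
    emit_tsv(profiles, "profiles.tsv")
    staging <- list(rule_accuracy = mean(profiles$predicted_state == profiles$state))
    cls <- tryCatch(fit_stage_classifier(profiles), error = function(e) NULL)
    if (!is.null(cls)) {
      n_boot <- sb$n_boot %||% 2000
      for (pr in cls$pairs$pair) {
        sc <- cls$scores[[pr]]
        ci <- bootstrap_auc_ci(sc$score, sc$label, n_boot = n_boot, seed = seed)
        staging[[paste0("auc_", pr)]] <-
          list(auc = cls$pairs$auc[cls$pairs$pair == pr],
               ci_lower = ci$lower, ci_upper = ci$upper, n_boot = n_boot)
      }
    }
    gc_tab <- tryCatch(group_compare(profiles), error = function(e) NULL)
    if (!is.null(gc_tab)) staging$group_tests <- gc_tab
    emit_json(staging, "staging.json")
    manifest$stages$stage <- list(path = "staging.json",
                                  n_donors = nrow(profiles))
    results$profiles <- profiles
    results$staging <- staging
    message(sprintf("stage: rule accuracy %.3f over %d donors",
                    staging$rule_accuracy, nrow(profiles)))

    cov_names <- block("associate", NULL)$covariates
    if (!is.null(cov_names)) {
      assoc <- lapply(cov_names, function(cv) {
        if (!cv %in% names(cohort$donors)) return(NULL)
        v <- cohort$donors[[cv]][match(profiles$donor_id, cohort$donors$donor_id)]
        pa <- tryCatch(pearson_assoc(profiles$proportion, v),
                       error = function(e) NULL)
        if (is.null(pa)) NULL else c(list(covariate = cv), pa)
      })
      assoc <- Filter(Negate(is.null), assoc)
      emit_json(assoc, "associations.json")
      manifest$stages$associate <- list(path = "associations.json")
      results$associations <- assoc
    }
  }

  # --- pseudobulk DE -------------------------------------------------------
  db <- block("de", NULL)
  if (!is.null(db) || isTRUE(cfg$de %||% FALSE)) db <- db %||% list()
  if (!is.null(db)) {
    de <- tryCatch(de_test(pseudobulk_aggregate(cohort, risk,
                                                db$min_cells %||% 10)),
                   error = function(e) fail("de", e))
    emit_tsv(de, "de.tsv")
    manifest$stages$de <- list(path = "de.tsv",
                               n_significant = sum(de$p_adj < 0.05, na.rm = TRUE))
    results$de <- de
    message(sprintf("de: %d/%d genes at adjusted p < 0.05",
                    sum(de$p_adj < 0.05, na.rm = TRUE), sum(!is.na(de$p))))
  }

  # --- subtype dynamics ----------------------------------------------------
  yb <- block("dynamics", NULL)
  if (!is.null(yb)) {
    sub <- subset_by_cell_type(cohort, cell_type)
    norm <- normalize_log(sub)
    clusters <- tryCatch(
      subtype_cluster(norm, n_neighbors = yb$n_neighbors %||% 15,
                      n_pcs = yb$n_pcs %||% 30,
                      resolution = yb$resolution %||% 1, seed = seed),
      error = function(e) fail("dynamics", e))
    dyn <- tryCatch(risk_aggregation_dynamics(clusters, risk, cohort),
                    error = function(e) fail("dynamics", e))
    emit_tsv(data.frame(cell_id = names(clusters),
                        cluster = as.integer(clusters)), "clusters.tsv")
    emit_tsv(as.data.frame(dyn), "dynamics.tsv")
    manifest$stages$dynamics <- list(path = "dynamics.tsv",
                                     n_clusters = length(unique(clusters)))
    results$dynamics <- dyn
    message(sprintf("dynamics: %d subtype clusters", length(unique(clusters))))
  }

  manifest$outputs <- as.list(tools::md5sum(sort(unique(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  out <- out_dir
  attr(out, "results") <- results
  invisible(out)
}
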