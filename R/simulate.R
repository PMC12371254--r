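#' Configuration for the synthetic multi-donor cohort simulator
#'
#' The simulator emulates the mixture structure the risk-cell framework
#' assumes: each donor's cells are a mixture of normal cells and cells
#' perturbed by a shared disease program, with the perturbed fraction
#' increasing along the ND -> preT2D -> T2D continuum.
#'
#' @param n_donors integer vector of donors per state `c(ND, preT2D, T2D)`
#'   (default `c(10, 10, 10)`).
#' @param cells_per_donor cells simulated per donor (default 200).
#' @param n_genes number of genes (default 1000).
#' @param n_perturbed_genes genes in the planted disease program
#'   (default 100).
#' @param effect_log2fc log2 fold-change applied to perturbed genes in risk
#'   cells (default 1.0, i.e. 2-fold).
#' @param risk_fraction per-state probability that a cell is a risk cell,
#'   `c(ND, preT2D, T2D)` (default `c(0.05, 0.15, 0.30)`, echoing the
#'   proportion bands used for rule-based staging).
#' @param nb_dispersion negative-binomial dispersion `alpha` with
#'   `Var = m + alpha * m^2` (default 0.5; 0 gives Poisson counts).
#' @param donor_effect_sd sd of per-donor, per-gene log-mean shifts — a
#'   donor expression signature unrelated to disease (default 0.15).
#' @param libsize_sd sd of per-cell log library-size factors (default 0.3).
#' @param cell_type label given to every simulated cell (default "beta").
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_donors = c(10, 10, 10),
                       cells_per_donor = 200,
                       n_genes = 1000,
                       n_perturbed_genes = 100,
                       effect_log2fc = 1.0,
                       risk_fraction = c(0.05, 0.15, 0.30),
                       nb_dispersion = 0.5,
                       donor_effect_sd = 0.15,
                       libsize_sd = 0.3,
                       cell_type = "beta",
                       seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              cells_per_donor = as.integer(cells_per_donor),
              n_genes = as.integer(n_genes),
              n_perturbed_genes = as.integer(n_perturbed_genes),
              effect_log2fc = as.numeric(effect_log2fc),
              risk_fraction = as.numeric(risk_fraction),
              nb_dispersion = as.numeric(nb_dispersion),
              donor_effect_sd = as.numeric(donor_effect_sd),
              libsize_sd = as.numeric(libsize_sd),
              cell_type = as.character(cell_type),
              seed = as.integer(seed))
  if (length(cfg$n_donors) != 3 || any(cfg$n_donors < 0))
    stop_value("invalid field n_donors: need 3 non-negative counts (ND, preT2D, T2D)")
  if (sum(cfg$n_donors) < 1) stop_value("invalid field n_donors: no donors")
  if (cfg$cells_per_donor < 1) stop_value("invalid field cells_per_donor")
  if (cfg$n_genes < 1) stop_value("invalid field n_genes")
  if (cfg$n_perturbed_genes < 0 || cfg$n_perturbed_genes > cfg$n_genes)
    stop_value("invalid field n_perturbed_genes: must be in [0, n_genes]")
  if (length(cfg$risk_fraction) != 3 ||
      any(cfg$risk_fraction < 0) || any(cfg$risk_fraction > 1))
    stop_value("invalid field risk_fraction: need 3 probabilities in [0,1]")
  if (cfg$nb_dispersion < 0) stop_value("invalid field nb_dispersion")
  if (cfg$donor_effect_sd < 0) stop_value("invalid field donor_effect_sd")
  if (cfg$libsize_sd < 0) stop_value("invalid field libsize_sd")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a multi-donor single-cell cohort with planted risk cells
#'
#' Generative model: baseline gene log-means are drawn once per run from
#' `N(log 0.5, 1)`; each donor adds a per-gene signature `N(0,
#' donor_effect_sd)`; each cell is flagged a risk cell with its donor
#' state's probability; risk cells have the perturbed genes' log-means
#' shifted by `effect_log2fc * log 2`; counts are drawn from a negative
#' binomial with mean `exp(log-mean) * libsize_factor` and dispersion
#' `alpha` (`Var = m + alpha m^2`). Risk status is i.i.d. within donor, so
#' realized donor fractions vary binomially around the configured targets.
#'
#' @param cfg a [sim_config()].
#' @return a list with `cohort` (a validated [new_cohort()]) and `truth`
#'   (`SimTruth`): `cells` (cell_id, is_risk_true), `perturbed_genes`, and
#'   `donor_fraction` (per-donor realized risk fraction).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  if (!inherits(cfg, "SimConfig")) cfg <- do.call(sim_config, cfg)
  with_seed(cfg$seed, {
    G <- cfg$n_genes
    gene_ids <- sprintf("g%04d", seq_len(G))
    base_logmean <- stats::rnorm(G, mean = log(0.5), sd = 1)
    perturbed <- sort(sample.int(G, cfg$n_perturbed_genes))
    shift <- numeric(G)
    shift[perturbed] <- cfg$effect_log2fc * log(2)

    states <- rep(c(0L, 1L, 2L), times = cfg$n_donors)
    D <- length(states)
    donor_ids <- sprintf("d%02d", seq_len(D))
    donor_eff <- matrix(stats::rnorm(D * G, sd = cfg$donor_effect_sd),
                        nrow = D)

    n_cells <- D * cfg$cells_per_donor
    cell_donor <- rep(seq_len(D), each = cfg$cells_per_donor)
    cell_ids <- sprintf("c%05d", seq_len(n_cells))
    p_risk <- cfg$risk_fraction[states + 1L][cell_donor]
    is_risk <- stats::rbinom(n_cells, 1L, p_risk) == 1L
    lib <- exp(stats::rnorm(n_cells, sd = cfg$libsize_sd))

    log_mu <- matrix(base_logmean, nrow = n_cells, ncol = G, byrow = TRUE) +
      donor_eff[cell_donor, , drop = FALSE]
    if (any(is_risk) && length(perturbed))
      log_mu[is_risk, ] <- sweep(log_mu[is_risk, , drop = FALSE], 2, shift, `+`)
    mu <- exp(log_mu) * lib
    counts <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(length(mu), lambda = mu)
    }
    counts <- matrix(counts, nrow = n_cells, ncol = G,
                     dimnames = list(cell_ids, gene_ids))

    cells <- data.frame(cell_id = cell_ids,
                        donor_id = donor_ids[cell_donor],
                        cell_type = cfg$cell_type,
                        stringsAsFactors = FALSE)
    donors <- data.frame(donor_id = donor_ids, state = states,
                         stringsAsFactors = FALSE)
    cohort <- new_cohort(Matrix::Matrix(counts, sparse = TRUE), cells, donors)
    truth <- structure(list(
      cells = data.frame(cell_id = cell_ids, is_risk_true = is_risk,
                         stringsAsFactors = FALSE),
      perturbed_genes = gene_ids[perturbed],
      donor_fraction = data.frame(
        donor_id = donor_ids, state = states,
        true_fraction = as.numeric(tapply(is_risk, cell_donor, mean)),
        stringsAsFactors = FALSE)
    ), class = "SimTruth")
    list(cohort = cohort, truth = truth)
  })
}
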