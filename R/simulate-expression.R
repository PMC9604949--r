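#' Parameters for the two-state bursting expression simulator
#'
#' The generator draws, for every donor x time point, a genes x cells UMI
#' matrix from a minimal two-state model of transcription: in each cell a
#' gene is "on" with a (gene-class, time)-dependent probability; "on" counts
#' are negative binomial around `burst_mean`, "off" counts are zero except
#' for a small leakage probability of a single stray UMI. Per-cell library
#' size, per-donor gene level and an optional shared latent factor acting on
#' a designated gene block provide, respectively, baseline gene-gene and
#' cell-cell correlation, donor-to-donor level differences, and a tunable
#' burst of gene-gene correlation at chosen time points.
#'
#' The default activity profile rises between the first two time points and
#' decays after mid-course, emulating the rise-then-fall of the number of
#' genes detected per cell observed in stimulated CD34+ progenitors.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_time cells per donor per time point.
#' @param time_points ordered, unique time labels.
#' @param p_active_per_time probability a gene is "on" at each time point:
#'   either a vector of length `length(time_points)` applied to every gene,
#'   or a classes x times matrix used together with `gene_class`.
#' @param gene_class integer class per gene (rows of `p_active_per_time`);
#'   default all genes in class 1.
#' @param burst_mean expected UMI count of an "on" gene (> 0).
#' @param dispersion negative-binomial size parameter (> 0); smaller means
#'   more overdispersed.
#' @param gene_mean_sdlog log-sd of per-gene base expression around
#'   `burst_mean` (0 = all genes share the burst mean).
#' @param n_donors number of donors.
#' @param donor_effect_sd log-sd of the per-gene multiplicative donor effect.
#' @param cell_size_sd log-sd of the per-cell library-size factor applied to
#'   all genes (models sequencing-depth / cell-size variation).
#' @param leakage probability an "off" gene yields one stray UMI in a cell.
#' @param correlated_block optional `list(genes=, time_points=, strength=)`:
#'   gene indices that share a per-cell lognormal latent factor of log-sd
#'   `strength` at the named time points (drives gene-gene correlation).
#' @param spike optional `list(genes=, time_points=, fc=)`: gene indices
#'   whose burst mean is multiplied by `fc` at the named time points
#'   (ground truth for differential expression).
#' @param qc_fail_rates named list of per-cell probabilities of failing each
#'   QC criterion in the emitted metadata (`reads`, `mito`, `ercc`).
#' @param seed integer RNG seed.
#' @return a list of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 2000,
                                  n_cells_per_time = 500,
                                  time_points = c("5h", "24h", "48h",
                                                  "72h", "96h"),
                                  p_active_per_time = c(0.05, 0.15, 0.23,
                                                        0.18, 0.14),
                                  gene_class = NULL,
                                  burst_mean = 5,
                                  dispersion = 2,
                                  gene_mean_sdlog = 0,
                                  n_donors = 2,
                                  donor_effect_sd = 0.1,
                                  cell_size_sd = 0.3,
                                  leakage = 0.01,
                                  correlated_block = NULL,
                                  spike = NULL,
                                  qc_fail_rates = list(reads = 0.04,
                                                       mito = 0.03,
                                                       ercc = 0.02),
                                  seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_cells_per_time <- assert_count(n_cells_per_time, "n_cells_per_time")
  stop_if(length(time_points) < 1L || anyDuplicated(time_points) > 0L,
          "`time_points` must be non-empty ordered unique labels")
  nt <- length(time_points)
  if (is.matrix(p_active_per_time)) {
    stop_if(ncol(p_active_per_time) != nt,
            "p_active_per_time matrix needs one column per time point")
    assert_prob(as.numeric(p_active_per_time), "p_active_per_time")
    stop_if(is.null(gene_class) || length(gene_class) != n_genes,
            "`gene_class` (length n_genes) required with a matrix profile")
    stop_if(any(gene_class < 1 | gene_class > nrow(p_active_per_time)),
            "`gene_class` out of range")
  } else {
    stop_if(length(p_active_per_time) != nt,
            "p_active_per_time needs one entry per time point")
    assert_prob(p_active_per_time, "p_active_per_time")
    p_active_per_time <- matrix(p_active_per_time, nrow = 1)
    gene_class <- rep(1L, n_genes)
  }
  stop_if(burst_mean <= 0, "`burst_mean` must be > 0")
  stop_if(dispersion <= 0, "`dispersion` must be > 0")
  stop_if(donor_effect_sd < 0, "`donor_effect_sd` must be >= 0")
  assert_prob(leakage, "leakage")
  if (!is.null(correlated_block)) {
    stop_if(!all(c("genes", "time_points", "strength") %in%
                   names(correlated_block)),
            "`correlated_block` needs genes, time_points, strength")
    stop_if(!all(correlated_block$time_points %in% time_points),
            "correlated_block time_points not in `time_points`")
  }
  if (!is.null(spike)) {
    stop_if(!all(c("genes", "time_points") %in% names(spike)),
            "`spike` needs genes and time_points")
    if (is.null(spike$fc)) spike$fc <- 4
    stop_if(!all(spike$time_points %in% time_points),
            "spike time_points not in `time_points`")
  }
  structure(list(n_genes = n_genes, n_cells_per_time = n_cells_per_time,
                 time_points = as.character(time_points),
                 p_active_per_time = p_active_per_time,
                 gene_class = as.integer(gene_class),
                 burst_mean = burst_mean, dispersion = dispersion,
                 gene_mean_sdlog = gene_mean_sdlog,
                 n_donors = assert_count(n_donors, "n_donors"),
                 donor_effect_sd = donor_effect_sd,
                 cell_size_sd = cell_size_sd, leakage = leakage,
                 correlated_block = correlated_block, spike = spike,
                 qc_fail_rates = qc_fail_rates,
                 seed = as.integer(seed)),
            class = "expression_sim_params")
}

#' Simulate UMI count matrices with known ground truth
#'
#' @param params an [expression_sim_params()] object.
#' @return a list of class `expression_sim` with elements
#'   * `matrices`: named list (`"<donor>_<time>"`) of [umi_matrix()] objects
#'     carrying simulated QC metadata;
#'   * `truth$gene`: per-gene table (class, per-time on-probability, spike
#'     and correlated-block membership);
#'   * `truth$on`: named list of logical genes x cells matrices recording
#'     the latent on/off draw behind each count matrix;
#'   * `params`: the input parameters.
#' Identical seeds give bit-identical output.
#' @export
simulate_expression <- function(params) {
  stop_if(!inherits(params, "expression_sim_params"),
          "`params` must come from expression_sim_params()")
  p <- params
  set.seed(p$seed)
  G <- p$n_genes; n <- p$n_cells_per_time; tps <- p$time_points
  gene_ids <- sprintf("gene%04d", seq_len(G))
  donors <- paste0("donor", seq_len(p$n_donors))

  ## gene-level draws shared across donors and times
  base_mu <- p$burst_mean *
    exp(stats::rnorm(G, -p$gene_mean_sdlog^2 / 2, p$gene_mean_sdlog))
  donor_fac <- matrix(exp(stats::rnorm(G * p$n_donors, 0, p$donor_effect_sd)),
                      nrow = G)

  in_block <- rep(FALSE, G)
  if (!is.null(p$correlated_block)) in_block[p$correlated_block$genes] <- TRUE
  spiked <- matrix(FALSE, G, length(tps), dimnames = list(gene_ids, tps))
  if (!is.null(p$spike))
    spiked[p$spike$genes,
           match(p$spike$time_points, tps)] <- TRUE

  p_act <- p$p_active_per_time[p$gene_class, , drop = FALSE]  # G x T
  colnames(p_act) <- tps

  matrices <- list(); on_truth <- list()
  for (d in seq_len(p$n_donors)) {
    for (ti in seq_along(tps)) {
      tp <- tps[ti]
      cell_ids <- sprintf("%s_%s_c%04d", donors[d], tp, seq_len(n))
      on <- matrix(stats::runif(G * n) < p_act[, ti], G, n,
                   dimnames = list(gene_ids, cell_ids))
      size_fac <- exp(stats::rnorm(n, 0, p$cell_size_sd))
      mu <- base_mu * donor_fac[, d]
      if (any(spiked[, ti])) mu[spiked[, ti]] <- mu[spiked[, ti]] * p$spike$fc
      mu_mat <- outer(mu, size_fac)
      if (!is.null(p$correlated_block) &&
          tp %in% p$correlated_block$time_points) {
        lat <- exp(stats::rnorm(n, 0, p$correlated_block$strength))
        mu_mat[in_block, ] <- mu_mat[in_block, , drop = FALSE] *
          rep(lat, each = sum(in_block))
      }
      counts <- matrix(0L, G, n, dimnames = list(gene_ids, cell_ids))
      if (any(on))
        counts[on] <- stats::rnbinom(sum(on), mu = mu_mat[on],
                                     size = p$dispersion)
      off <- !on
      if (p$leakage > 0 && any(off)) {
        leak <- off & matrix(stats::runif(G * n) < p$leakage, G, n)
        counts[leak] <- 1L
      }
      meta <- simulate_cell_meta(counts, p$qc_fail_rates)
      key <- paste0(donors[d], "_", tp)
      matrices[[key]] <- umi_matrix(counts, gene_ids, cell_ids,
                                    donor = donors[d], time_point = tp,
                                    cell_meta = meta)
      on_truth[[key]] <- on
    }
  }
  gene_truth <- data.frame(gene_id = gene_ids, class = p$gene_class,
                           in_correlated_block = in_block,
                           stringsAsFactors = FALSE)
  gene_truth <- cbind(gene_truth,
                      stats::setNames(as.data.frame(p_act),
                                      paste0("p_active_", tps)),
                      stats::setNames(as.data.frame(spiked),
                                      paste0("spiked_", tps)))
  structure(list(matrices = matrices,
                 truth = list(gene = gene_truth, on = on_truth),
                 params = p),
            class = "expression_sim")
}

## Per-cell QC metadata: most cells pass; a small designated fraction fails
## each criterion. Read totals scale with the UMI total of the cell.
simulate_cell_meta <- function(counts, fail_rates) {
  n <- ncol(counts)
  umi_tot <- colSums(counts)
  total_reads <- pmax(round((umi_tot + 50) *
                              exp(stats::rnorm(n, log(400), 0.25))), 1)
  total_reads <- pmax(total_reads, 80000 + round(stats::runif(n, 0, 4e5)))
  mito <- stats::rbeta(n, 2, 38)
  ercc <- pmin(stats::runif(n, 0.75, 0.99), 1)
  fail_reads <- stats::runif(n) < fail_rates$reads
  fail_mito <- stats::runif(n) < fail_rates$mito
  fail_ercc <- stats::runif(n) < fail_rates$ercc
  total_reads[fail_reads] <- round(stats::runif(sum(fail_reads), 2e4, 79999))
  mito[fail_mito] <- stats::runif(sum(fail_mito), 0.101, 0.35)
  ercc[fail_ercc] <- stats::runif(sum(fail_ercc), 0.2, 0.6)
  data.frame(cell_id = colnames(counts), total_reads = total_reads,
             mito_fraction = mito, ercc_pearson = ercc,
             stringsAsFactors = FALSE)
}
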