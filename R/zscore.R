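#' Per-gene Z-score of expression change between two time points
#'
#' For each gene the statistic is
#' `z = (mean(UMI at t2) - mean(UMI at t1)) / sqrt(sd(t2)^2 + sd(t1)^2)`,
#' where mean and sd are taken over the cells of one donor at each time
#' point and sd is the sample (n-1) standard deviation. The score is
#' antisymmetric under swapping the two time points. When both sds are
#' zero the score is 0 if the means agree, otherwise it is recorded as a
#' signed `sentinel` value and flagged (preserving DE direction without
#' propagating infinities).
#'
#' @param matrix_t1,matrix_t2 [umi_matrix()] objects for the same donor
#'   sharing one gene universe, each with at least 2 cells.
#' @param sentinel magnitude used for the zero-denominator case (default
#'   12, i.e. the DE threshold 2 plus 10).
#' @return a data.frame: `gene_id`, `z`, `zero_denominator` (logical).
#' @export
zscore <- function(matrix_t1, matrix_t2, sentinel = 12) {
  stop_if(!inherits(matrix_t1, "umi_matrix") ||
            !inherits(matrix_t2, "umi_matrix"),
          "inputs must be umi_matrix objects")
  stop_if(!identical(matrix_t1$gene_ids, matrix_t2$gene_ids),
          "mismatched gene universes")
  stop_if(ncol(matrix_t1$counts) < 2L || ncol(matrix_t2$counts) < 2L,
          "each matrix needs at least 2 cells")
  m1 <- as.matrix(matrix_t1$counts); m2 <- as.matrix(matrix_t2$counts)
  num <- rowMeans(m2) - rowMeans(m1)
  den <- sqrt(row_sds(m1)^2 + row_sds(m2)^2)
  zero_den <- den == 0
  z <- num / den
  z[zero_den] <- sign(num[zero_den]) * sentinel  # sign(0) = 0
  data.frame(gene_id = matrix_t1$gene_ids, z = z,
             zero_denominator = zero_den, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes from per-donor Z-scores
#'
#' Donor Z-scores are combined by an unweighted arithmetic mean and genes
#' are flagged `up` when `mean_z >= threshold`, `down` when
#' `mean_z <= -threshold` (boundaries inclusive), `none` otherwise.
#'
#' @param z_by_donor a [zscore()] data.frame or list of them (one per
#'   donor) sharing a gene universe.
#' @param threshold DE threshold on the mean Z-score (default 2).
#' @param interval optional `c(t1, t2)` labels recorded in the output.
#' @return a data.frame: `gene_id`, per-donor `z_<i>` columns, `mean_z`,
#'   `de_flag` (factor up/down/none), and interval columns `t1`, `t2`.
#' @export
call_de <- function(z_by_donor, threshold = 2, interval = c(NA, NA)) {
  if (is.data.frame(z_by_donor)) z_by_donor <- list(z_by_donor)
  stop_if(length(z_by_donor) == 0L, "no donor z-scores supplied")
  genes <- z_by_donor[[1]]$gene_id
  zs <- vapply(z_by_donor, function(d) {
    stop_if(!identical(d$gene_id, genes), "no common gene universe")
    d$z
  }, numeric(length(genes)))
  zs <- matrix(zs, nrow = length(genes))
  mean_z <- rowMeans(zs)
  de_flag <- factor(ifelse(mean_z >= threshold, "up",
                           ifelse(mean_z <= -threshold, "down", "none")),
                    levels = c("up", "down", "none"))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(zs))) out[[paste0("z_", i)]] <- zs[, i]
  out$mean_z <- mean_z
  out$de_flag <- de_flag
  out$t1 <- interval[1]; out$t2 <- interval[2]
  out
}

#' Classify genes by the DE status of their upstream TFs
#'
#' Network edges are first filtered to confidence strictly greater than
#' `min_confidence`. A gene is `DE-TF-targeted` when at least one surviving
#' incoming edge originates from a TF-coding gene called DE;
#' `nonDE-TF-targeted-only` when it has at least one surviving edge but
#' none from a DE TF; `untargeted` otherwise. The three classes partition
#' the DE-record gene universe. Edges whose TF is absent from the gene
#' universe raise a warning and are kept with the TF treated as non-DE.
#'
#' @param de_records a [call_de()] data.frame.
#' @param network a `tf_network` (from [simulate_tf_network()]) or a list
#'   with an `edges` data.frame (`tf`, `target`, `confidence`).
#' @param min_confidence strict lower bound on edge confidence (default
#'   0.5).
#' @return a list with `gene_class` (data.frame: `gene_id`, `class`) over
#'   the DE-record universe and `tf_status` (data.frame: `tf`, `de` flag)
#'   for every TF appearing in a surviving edge.
#' @export
classify_tf_status <- function(de_records, network, min_confidence = 0.5) {
  edges <- if (is.data.frame(network)) network else network$edges
  stop_if(!all(c("tf", "target", "confidence") %in% names(edges)),
          "network edges need tf, target, confidence")
  edges <- edges[edges$confidence > min_confidence, , drop = FALSE]
  universe <- de_records$gene_id
  de_genes <- de_records$gene_id[de_records$de_flag != "none"]
  missing_tf <- setdiff(unique(edges$tf), universe)
  if (length(missing_tf) > 0)
    warning(length(missing_tf),
            " TF id(s) absent from the gene universe; treated as non-DE")
  tf_de <- unique(edges$tf) %in% de_genes
  tf_status <- data.frame(tf = unique(edges$tf), de = tf_de,
                          stringsAsFactors = FALSE)
  de_tfs <- tf_status$tf[tf_status$de]
  targeted <- universe %in% edges$target
  de_tf_targeted <- universe %in% edges$target[edges$tf %in% de_tfs]
  class <- ifelse(de_tf_targeted, "DE-TF-targeted",
                  ifelse(targeted, "nonDE-TF-targeted-only", "untargeted"))
  list(gene_class = data.frame(gene_id = universe, class = class,
                               stringsAsFactors = FALSE),
       tf_status = tf_status)
}
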