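#' Remove low-quality cells from a UMI matrix
#'
#' A cell is retained only if it satisfies all three criteria:
#' `total_reads >= min_total_reads` (cells with *less than* the threshold
#' are removed), `mito_fraction <= max_mito_fraction` (*more than* the
#' threshold triggers removal), and `ercc_pearson > min_ercc_pearson`
#' (only cells strictly above are retained). The gene set is unchanged and
#' the operation is idempotent.
#'
#' @param matrix a [umi_matrix()] with complete `cell_meta`.
#' @param thresholds a [qc_thresholds()] object.
#' @return a list with `matrix` (the filtered [umi_matrix()]) and `removed`
#'   (data.frame: `cell_id`, `reason` — the first failing criterion, in the
#'   order total_reads, mito_fraction, ercc_pearson).
#' @export
filter_cells <- function(matrix, thresholds = qc_thresholds()) {
  stop_if(!inherits(matrix, "umi_matrix"), "`matrix` must be a umi_matrix")
  meta <- matrix$cell_meta
  stop_if(is.null(meta), "cell metadata missing: cell_meta is NULL")
  for (f in c("total_reads", "mito_fraction", "ercc_pearson")) {
    stop_if(!f %in% names(meta) || anyNA(meta[[f]]),
            sprintf("cell metadata field `%s` missing or incomplete", f))
  }
  fail_reads <- meta$total_reads < thresholds$min_total_reads
  fail_mito <- meta$mito_fraction > thresholds$max_mito_fraction
  fail_ercc <- meta$ercc_pearson <= thresholds$min_ercc_pearson
  reason <- rep(NA_character_, nrow(meta))
  reason[fail_ercc] <- "ercc_pearson"
  reason[fail_mito] <- "mito_fraction"
  reason[fail_reads] <- "total_reads"  # first criterion wins
  keep <- is.na(reason)
  list(matrix = subset_cells(matrix, keep),
       removed = data.frame(cell_id = matrix$cell_ids[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Identify detectable genes across a collection of UMI matrices
#'
#' A gene is detectable iff, aggregating over all cells of all supplied
#' matrices, (i) at least `gene_min_cells_multi_umi` cells contain more
#' than a single UMI (count >= 2) and (ii) the gene has at least
#' `gene_min_total_reads` reads in total.
#'
#' @param matrices a [umi_matrix()] or list of them sharing one gene
#'   universe (same ids in the same order).
#' @param thresholds a [qc_thresholds()] object.
#' @return character vector of detectable gene ids.
#' @export
detectable_genes <- function(matrices, thresholds = qc_thresholds()) {
  if (inherits(matrices, "umi_matrix")) matrices <- list(matrices)
  stop_if(length(matrices) == 0L, "no matrices supplied")
  universe <- matrices[[1]]$gene_ids
  for (m in matrices) {
    stop_if(!identical(m$gene_ids, universe),
            "matrices do not share a gene universe")
  }
  n_multi <- Reduce(`+`, lapply(matrices,
                                function(m) rowSums(m$counts >= 2)))
  total <- Reduce(`+`, lapply(matrices, function(m) rowSums(m$counts)))
  universe[n_multi >= thresholds$gene_min_cells_multi_umi &
             total >= thresholds$gene_min_total_reads]
}

#' Genes detected per cell, with mean and standard deviation
#'
#' A gene counts as detected in a cell when its UMI count is at least 1.
#'
#' @param matrix a [umi_matrix()].
#' @return a list with `per_cell` (named integer vector of detected-gene
#'   counts), `mean`, `sd` (sample sd; `NA` for a single cell), `donor`
#'   and `time_point`.
#' @export
genes_per_cell_summary <- function(matrix) {
  stop_if(!inherits(matrix, "umi_matrix"), "`matrix` must be a umi_matrix")
  stop_if(ncol(matrix$counts) == 0L || nrow(matrix$counts) == 0L,
          "empty matrix")
  per_cell <- colSums(matrix$counts >= 1)
  names(per_cell) <- matrix$cell_ids
  list(per_cell = per_cell, mean = mean(per_cell),
       sd = stats::sd(per_cell),
       donor = matrix$donor, time_point = matrix$time_point)
}
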