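#' UMI count matrix for one donor and one time point
#'
#' Lightweight container for a genes x cells matrix of non-negative integer
#' UMI counts together with the per-cell quality-control metadata the cell
#' filters operate on (total mapped reads, mitochondrial read fraction, and
#' the Pearson correlation of observed vs expected ERCC spike-in counts).
#'
#' @param counts genes x cells numeric matrix (or Matrix sparse matrix) of
#'   non-negative integer counts. Row and column names, when present, seed
#'   `gene_ids` / `cell_ids`.
#' @param gene_ids character vector of stable gene identifiers (rows).
#' @param cell_ids character vector of cell barcodes (columns).
#' @param donor donor label.
#' @param time_point time-point label (e.g. `"24h"`).
#' @param cell_meta `data.frame` with one row per cell; recognised columns
#'   are `total_reads`, `mito_fraction` and `ercc_pearson`. May be `NULL`
#'   when no QC filtering is intended.
#' @return an object of class `umi_matrix`.
#' @export
umi_matrix <- function(counts, gene_ids = rownames(counts),
                       cell_ids = colnames(counts),
                       donor = "donor1", time_point = "0h",
                       cell_meta = NULL) {
  stop_if(is.null(dim(counts)), "`counts` must be a matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  stop_if(length(gene_ids) != nrow(counts),
          "`gene_ids` length must match nrow(counts)")
  stop_if(length(cell_ids) != ncol(counts),
          "`cell_ids` length must match ncol(counts)")
  cx <- if (inherits(counts, "Matrix")) Matrix::summary(counts)$x else counts
  stop_if(any(cx < 0) || any(cx != round(cx)),
          "`counts` must contain non-negative integers")
  if (!is.null(cell_meta)) {
    stop_if(!is.data.frame(cell_meta) || nrow(cell_meta) != ncol(counts),
            "`cell_meta` must be a data.frame with one row per cell")
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 donor = donor, time_point = time_point,
                 cell_meta = cell_meta),
            class = "umi_matrix")
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("<umi_matrix> %d genes x %d cells | donor=%s time=%s | meta: %s\n",
              nrow(x$counts), ncol(x$counts), x$donor, x$time_point,
              if (is.null(x$cell_meta)) "none"
              else paste(names(x$cell_meta), collapse = ", ")))
  invisible(x)
}

## subset cells, keeping metadata in register
subset_cells <- function(x, keep) {
  umi_matrix(x$counts[, keep, drop = FALSE],
             gene_ids = x$gene_ids,
             cell_ids = x$cell_ids[keep],
             donor = x$donor, time_point = x$time_point,
             cell_meta = if (is.null(x$cell_meta)) NULL
                         else x$cell_meta[keep, , drop = FALSE])
}

#' Quality-control thresholds for cell and gene filtering
#'
#' Defaults follow the study design this package re-implements: cells with
#' fewer than 80,000 total reads, more than 10% mitochondrial reads, or an
#' ERCC spike-in Pearson correlation not strictly above 0.6 are removed;
#' a gene is "detectable" when at least `gene_min_cells_multi_umi` cells
#' carry more than a single UMI and the gene has at least
#' `gene_min_total_reads` reads in total.
#'
#' @param min_total_reads minimum total reads per cell (cells strictly below
#'   are removed). Default 80000.
#' @param max_mito_fraction maximum mitochondrial read fraction (cells
#'   strictly above are removed). Default 0.10.
#' @param min_ercc_pearson minimum ERCC spike-in correlation (only cells
#'   strictly above are retained). Default 0.6.
#' @param gene_min_cells_multi_umi minimum number of cells with >= 2 UMIs
#'   for a gene to be detectable. Default 2.
#' @param gene_min_total_reads minimum summed reads for a detectable gene.
#'   Default 5.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_total_reads = 80000,
                          max_mito_fraction = 0.10,
                          min_ercc_pearson = 0.6,
                          gene_min_cells_multi_umi = 2,
                          gene_min_total_reads = 5) {
  stop_if(!all(is.finite(c(min_total_reads, max_mito_fraction,
                           min_ercc_pearson, gene_min_cells_multi_umi,
                           gene_min_total_reads))),
          "all thresholds must be finite")
  structure(list(min_total_reads = min_total_reads,
                 max_mito_fraction = max_mito_fraction,
                 min_ercc_pearson = min_ercc_pearson,
                 gene_min_cells_multi_umi = gene_min_cells_multi_umi,
                 gene_min_total_reads = gene_min_total_reads),
            class = "qc_thresholds")
}
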