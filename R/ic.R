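#' All pairwise Pearson correlations along one axis of a count matrix
#'
#' Computes the `C(n,2)` Pearson coefficients between all pairs of gene
#' vectors (rows, across cells) or cell state vectors (columns, across
#' genes). Pairs involving a zero-variance vector are returned as `NA`
#' ("undefined") and are excluded by downstream consumers rather than
#' imputed.
#'
#' @param matrix a [umi_matrix()] or plain numeric matrix (genes x cells).
#' @param axis `"genes"` or `"cells"`.
#' @return a data.frame with columns `i`, `j` (1-based vector indices,
#'   `i < j`) and `r`.
#' @export
pairwise_pearson <- function(matrix, axis = c("genes", "cells")) {
  axis <- match.arg(axis)
  m <- if (inherits(matrix, "umi_matrix")) matrix$counts else matrix
  m <- as.matrix(m)
  if (axis == "genes") m <- t(m)  # vectors become columns
  stop_if(ncol(m) < 2L, "need at least 2 ", axis)
  cc <- suppressWarnings(stats::cor(m))  # zero-variance pairs -> NA
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], r = cc[idx])
}

#' Index for critical transitions (Ic) per cell cluster
#'
#' Within each cluster, all gene-gene and all cell-cell Pearson
#' correlations are computed from the filtered count matrix; only
#' coefficients strictly greater than `threshold` (default 0.70) are
#' retained, and `Ic = mean(retained gene-gene r) / mean(retained
#' cell-cell r)`. A maximum of the index along a time course flags
#' proximity to a critical state transition. Clusters with fewer than 2
#' cells or genes, or with an empty retained set on either axis, are
#' returned flagged with `ic = NA` rather than dropped.
#'
#' @param matrix a [umi_matrix()] (or plain matrix) covering all clustered
#'   cells.
#' @param clusters cluster assignment: either a vector of labels (one per
#'   cell, in column order) or a two-column data.frame `(cell_id, cluster)`.
#' @param threshold retained-correlation threshold in (0, 1); strictly
#'   greater wins.
#' @param use_abs retain on `|r| > threshold` instead of signed `r`.
#' @param log1p apply `log1p` to the counts first (off by default: the
#'   index is defined on the filtered count matrix).
#' @return a data.frame with one row per cluster: `cluster`, `ic`,
#'   `mean_gene_gene_r`, `mean_cell_cell_r`, `n_gene_pairs_retained`,
#'   `n_cell_pairs_retained`, `threshold`, `flag` (`"ok"` or the reason
#'   the value is undefined).
#' @export
compute_ic <- function(matrix, clusters, threshold = 0.70,
                       use_abs = FALSE, log1p = FALSE) {
  stop_if(!(threshold > 0 && threshold < 1), "`threshold` must be in (0,1)")
  m <- if (inherits(matrix, "umi_matrix")) matrix$counts else matrix
  m <- as.matrix(m)
  if (log1p) m <- log1p(m)
  if (is.data.frame(clusters)) {
    stop_if(ncol(clusters) < 2L, "cluster table needs (cell_id, cluster)")
    stop_if(!all(clusters[[1]] %in% colnames(m)),
            "cluster table names cells absent from the matrix")
    lab <- rep(NA, ncol(m))
    lab[match(clusters[[1]], colnames(m))] <- clusters[[2]]
  } else {
    stop_if(length(clusters) != ncol(m),
            "`clusters` must label every cell")
    lab <- clusters
  }
  out <- lapply(sort(unique(stats::na.omit(lab))), function(cl) {
    sub <- m[, which(lab == cl), drop = FALSE]
    ic_one_cluster(sub, cl, threshold, use_abs)
  })
  do.call(rbind, out)
}

ic_one_cluster <- function(sub, cl, threshold, use_abs) {
  res <- data.frame(cluster = cl, ic = NA_real_,
                    mean_gene_gene_r = NA_real_,
                    mean_cell_cell_r = NA_real_,
                    n_gene_pairs_retained = 0L,
                    n_cell_pairs_retained = 0L,
                    threshold = threshold, flag = "ok",
                    stringsAsFactors = FALSE)
  if (ncol(sub) < 2L || nrow(sub) < 2L) {
    res$flag <- "too_few_cells_or_genes"
    return(res)
  }
  gg <- pairwise_pearson(sub, "genes")$r
  cc <- pairwise_pearson(sub, "cells")$r
  keep <- function(r) {
    r <- r[!is.na(r)]
    if (use_abs) r[abs(r) > threshold] else r[r > threshold]
  }
  gg <- keep(gg); cc <- keep(cc)
  res$n_gene_pairs_retained <- length(gg)
  res$n_cell_pairs_retained <- length(cc)
  if (length(gg) == 0L || length(cc) == 0L) {
    res$flag <- "empty_retained_set"
    return(res)
  }
  res$mean_gene_gene_r <- mean(gg)
  res$mean_cell_cell_r <- mean(cc)
  res$ic <- res$mean_gene_gene_r / res$mean_cell_cell_r
  res
}
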