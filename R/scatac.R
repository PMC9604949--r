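#' Per-peak cell-sharing counts and category medians
#'
#' The number of cells sharing a peak is its column sum in the binary
#' cell x peak incidence matrix. Medians are reported over all peaks and,
#' when a per-peak category is available, over promoter and intergenic
#' peaks (midpoint-of-order-statistics convention for even counts, as in
#' [stats::median()]).
#'
#' @param incidence a `cell_peak_incidence` (from [simulate_scatac()] or
#'   [read_incidence_mtx()]) or a binary cells x peaks matrix.
#' @param categories optional per-peak category character vector (e.g.
#'   from [annotate_peaks()]; the catalog's own `category` column is used
#'   when present).
#' @return a list: `per_peak` (named numeric vector of sharing counts),
#'   `median_all`, `median_promoter`, `median_intergenic` (the latter two
#'   `NA` when no category information is available).
#' @export
sharing_counts <- function(incidence, categories = NULL) {
  inc <- if (inherits(incidence, "cell_peak_incidence")) {
    if (is.null(categories) && !is.null(incidence$peaks$category))
      categories <- incidence$peaks$category
    incidence$incidence
  } else incidence
  stop_if(is.null(dim(inc)) || ncol(inc) == 0L, "empty peak catalog")
  per_peak <- Matrix::colSums(inc != 0)
  med <- function(x) if (length(x) == 0L) NA_real_ else stats::median(x)
  list(per_peak = per_peak,
       median_all = med(per_peak),
       median_promoter = if (is.null(categories)) NA_real_
         else med(per_peak[categories == "promoter"]),
       median_intergenic = if (is.null(categories)) NA_real_
         else med(per_peak[categories == "intergenic"]))
}

#' Concordance of a single-cell peak catalog with bulk peaks
#'
#' A single-cell peak is bulk-supported iff it overlaps a bulk peak by at
#' least 1 bp. The recovery fraction is the share of bulk peaks overlapped
#' by at least one single-cell peak. Sharing-count medians are reported
#' separately for bulk-supported and single-cell-only peaks.
#'
#' @param incidence a `cell_peak_incidence` whose `peaks` slot holds the
#'   single-cell catalog.
#' @param bulk bulk peak `GRanges`.
#' @return a list: `flag` (per single-cell peak, `"bulk-supported"` or
#'   `"single-cell-only"`), `recovery_fraction`,
#'   `median_bulk_supported`, `median_sc_only`.
#' @export
bulk_concordance <- function(incidence, bulk) {
  stop_if(!inherits(incidence, "cell_peak_incidence"),
          "`incidence` must be a cell_peak_incidence")
  sc <- incidence$peaks
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(sc))),
                 unique(as.character(GenomicRanges::seqnames(bulk))))
  stop_if(length(bad) > 0 && length(bulk) > 0,
          "chromosome mismatch; offenders: ", paste(bad, collapse = ", "))
  supported <- GenomicRanges::countOverlaps(sc, bulk) > 0
  recovered <- GenomicRanges::countOverlaps(bulk, sc) > 0
  share <- sharing_counts(incidence)$per_peak
  med <- function(x) if (length(x) == 0L) NA_real_ else stats::median(x)
  list(flag = ifelse(supported, "bulk-supported", "single-cell-only"),
       recovery_fraction = if (length(bulk) == 0L) NaN
         else mean(recovered),
       median_bulk_supported = med(share[supported]),
       median_sc_only = med(share[!supported]))
}
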