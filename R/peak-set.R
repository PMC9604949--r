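#' Construct a peak set from BED-convention coordinates
#'
#' All interval inputs in this package use the BED convention (0-based,
#' half-open) at the interface; internally intervals are held as
#' `GenomicRanges::GRanges` (1-based, closed). A peak's "size" is its read
#' count.
#'
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param read_count non-negative read counts (default 0).
#' @param donor,time_point labels attached to every peak.
#' @param seqlengths optional named vector of chromosome lengths (bp).
#' @return a `GRanges` with metadata columns `read_count`, `donor`,
#'   `time_point`.
#' @export
peak_set <- function(chrom, start, end, read_count = 0,
                     donor = NA_character_, time_point = NA_character_,
                     seqlengths = NULL) {
  stop_if(any(start >= end), "peak intervals need start < end")
  stop_if(any(start < 0), "peak starts must be >= 0")
  stop_if(any(read_count < 0), "read counts must be non-negative")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    read_count = rep_len(as.numeric(read_count), length(chrom)),
    donor = rep_len(donor, length(chrom)),
    time_point = rep_len(time_point, length(chrom)))
  if (!is.null(seqlengths)) {
    stop_if(!all(as.character(GenomicRanges::seqnames(gr)) %in%
                   names(seqlengths)),
            "peak chromosome absent from `seqlengths`")
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    stop_if(any(end > seqlengths[as.character(GenomicRanges::seqnames(gr))]),
            "peak beyond chromosome bounds")
  }
  gr
}

#' BED-convention start/end of a GRanges
#' @param gr a `GRanges`.
#' @return integer vector of 0-based starts (`bed_start`) or half-open ends
#'   (`bed_end`).
#' @export
bed_start <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname bed_start
#' @export
bed_end <- function(gr) GenomicRanges::end(gr)

#' Construct a genomic feature annotation
#'
#' @param chrom,start,end BED-convention intervals.
#' @param category feature category, one of `"promoter"`, `"exon"`,
#'   `"intron"`, `"CpG"`, `"CTCF"`.
#' @param gene_id gene identifier; required (non-NA) for promoter records.
#' @return a `GRanges` with metadata columns `category` and `gene_id`.
#' @export
feature_annotation <- function(chrom, start, end, category,
                               gene_id = NA_character_) {
  cats <- c("promoter", "exon", "intron", "CpG", "CTCF")
  stop_if(!all(category %in% cats),
          "`category` must be one of: ", paste(cats, collapse = ", "))
  gene_id <- rep_len(gene_id, length(chrom))
  stop_if(any(category == "promoter" & is.na(gene_id)),
          "promoter records must carry a gene_id")
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    category = category, gene_id = gene_id)
}
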