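#' Donor-reproducible peak regions (bp-wise intersection)
#'
#' Returns the maximal genomic segments covered by at least one peak in
#' *every* donor at the same time point — the base-pair-wise intersection
#' across donors, merged when contiguous. Each output region carries the
#' summed read counts of all contributing donor peaks. The operation is
#' symmetric in donor order and idempotent.
#'
#' @param peaksets list of peak `GRanges`, one per donor (>= 2).
#' @return a peak `GRanges` with `read_count` summed over contributing
#'   donor peaks (donor/time metadata taken from the first set). Empty
#'   when any donor has no peaks (with a warning).
#' @export
reproducible_peaks <- function(peaksets) {
  stop_if(!is.list(peaksets) || length(peaksets) < 2L,
          "need peak sets from at least 2 donors")
  if (any(vapply(peaksets, length, 1L) == 0L)) {
    warning("a donor has an empty peak set; intersection is empty")
    return(GenomicRanges::GRanges())
  }
  common <- Reduce(function(a, b)
    GenomicRanges::intersect(GenomicRanges::reduce(a),
                             GenomicRanges::reduce(b)),
    peaksets)
  if (length(common) == 0L) return(common)
  all_peaks <- suppressWarnings(do.call(c, unname(lapply(peaksets,
    function(g) GenomicRanges::granges(g, use.mcols = FALSE)))))
  rc <- unlist(lapply(peaksets, function(g) g$read_count))
  hits <- GenomicRanges::findOverlaps(common, all_peaks)
  sums <- rep(0, length(common))
  agg <- tapply(rc[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  common$read_count <- sums
  common$donor <- "intersection"
  common$time_point <- peaksets[[1]]$time_point[1]
  common
}

#' Annotate peaks against genomic features (multi-category)
#'
#' A peak is assigned every feature category it overlaps by at least
#' `min_overlap` bp, so category totals can exceed the number of peaks.
#' A peak overlapping no feature is `intergenic` — a category exclusive
#' of all others.
#'
#' @param peaks peak `GRanges`.
#' @param annotation a [feature_annotation()] `GRanges`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return a list with `per_peak` (list of category character vectors, one
#'   per peak) and `totals` (named integer vector over promoter, exon,
#'   intron, CpG, CTCF, intergenic).
#' @export
annotate_peaks <- function(peaks, annotation, min_overlap = 1L) {
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(peaks))),
                 unique(as.character(GenomicRanges::seqnames(annotation))))
  stop_if(length(bad) > 0,
          "unknown chromosome(s) in peaks: ", paste(bad, collapse = ", "))
  cats <- c("promoter", "exon", "intron", "CpG", "CTCF")
  hits <- GenomicRanges::findOverlaps(peaks, annotation,
                                      minoverlap = min_overlap)
  per_peak <- rep(list(character(0)), length(peaks))
  if (length(hits) > 0) {
    sp <- split(annotation$category[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    per_peak[as.integer(names(sp))] <- lapply(sp, function(x)
      intersect(cats, unique(x)))  # stable category order, deduplicated
  }
  none <- lengths(per_peak) == 0L
  per_peak[none] <- list("intergenic")
  totals <- vapply(c(cats, "intergenic"), function(cat)
    sum(vapply(per_peak, function(x) cat %in% x, logical(1))), integer(1))
  list(per_peak = per_peak, totals = totals)
}

#' Per-promoter open/closed calls at each time point
#'
#' A promoter is open at a time point iff at least one peak of that time
#' point's (donor-reproducible) peak set overlaps it by >= `min_overlap`
#' bp.
#'
#' @param peaksets_by_time named list of peak `GRanges`, one per time
#'   point, in time order.
#' @param annotation a [feature_annotation()] `GRanges`; only promoter
#'   records are used.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return a list with `open` (promoters x time points logical matrix) and
#'   `promoters` (the promoter `GRanges`, row order of `open`).
#' @export
promoter_open_calls <- function(peaksets_by_time, annotation,
                                min_overlap = 1L) {
  prom <- annotation[annotation$category == "promoter"]
  stop_if(length(prom) == 0L, "annotation contains no promoters")
  tps <- names(peaksets_by_time)
  if (is.null(tps)) tps <- paste0("t", seq_along(peaksets_by_time))
  open <- vapply(peaksets_by_time, function(pk) {
    if (length(pk) == 0L) return(rep(FALSE, length(prom)))
    GenomicRanges::countOverlaps(prom, pk, minoverlap = min_overlap) > 0
  }, logical(length(prom)))
  open <- matrix(open, nrow = length(prom),
                 dimnames = list(prom$gene_id, tps))
  list(open = open, promoters = prom)
}

#' Classify promoters into the four accessibility configurations
#'
#' The ordered pair of open/closed states at two consecutive time points
#' assigns each promoter exactly one of `open-open`, `open-closed`,
#' `closed-open`, `closed-closed`; the four classes partition the catalog.
#'
#' @param open_calls result of [promoter_open_calls()].
#' @param t1,t2 column labels (or indices) of the two time points.
#' @return a data.frame: `gene_id`, `config`, `t1`, `t2` — one row per
#'   promoter. Multi-promoter genes can carry several (possibly different)
#'   configurations.
#' @export
classify_promoter_configs <- function(open_calls, t1, t2) {
  open <- open_calls$open
  o1 <- open[, t1]; o2 <- open[, t2]
  config <- ifelse(o1, ifelse(o2, "open-open", "open-closed"),
                   ifelse(o2, "closed-open", "closed-closed"))
  tn <- colnames(open)
  lab <- function(t) if (is.numeric(t) && !is.null(tn)) tn[t] else t
  data.frame(gene_id = open_calls$promoters$gene_id, config = config,
             t1 = lab(t1), t2 = lab(t2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene-level promoter configurations
#'
#' Collapses per-promoter configurations to the gene level: a gene carries
#' every configuration observed for at least one of its promoters (so a
#' multi-promoter gene can appear in more than one class).
#'
#' @param promoter_configs result of [classify_promoter_configs()].
#' @return a data.frame: `gene_id`, `config` (unique pairs).
#' @export
gene_configs <- function(promoter_configs) {
  unique(promoter_configs[!is.na(promoter_configs$gene_id),
                          c("gene_id", "config")])
}

#' Presence-pattern trajectories of peaks across time points
#'
#' Peaks at the same genomic position across time points are linked by
#' transitive >= 1 bp overlap chaining (each chain is a maximal run of
#' mutually overlapping peaks pooled over all time points). Every chain
#' gets a presence bit pattern over the time points, a per-time read-count
#' trace (0 where absent), and a persistent flag (present at every time
#' point).
#'
#' @param peaksets_by_time named list of (donor-reproducible) peak
#'   `GRanges` in time order.
#' @return a list with `chains` (data.frame: `chrom`, `start`, `end` in
#'   BED convention, `pattern`, `persistent`, one `rc_<time>` column per
#'   time point) and `persistent_fraction`.
#' @export
peak_trajectories <- function(peaksets_by_time) {
  tps <- names(peaksets_by_time)
  stop_if(is.null(tps), "`peaksets_by_time` must be a named list")
  pool <- suppressWarnings(do.call(c, unname(lapply(peaksets_by_time,
    function(g) GenomicRanges::granges(g, use.mcols = FALSE)))))
  if (length(pool) == 0L)
    return(list(chains = data.frame(), persistent_fraction = NaN))
  chains <- GenomicRanges::reduce(pool)
  present <- matrix(FALSE, length(chains), length(tps))
  rc <- matrix(0, length(chains), length(tps))
  for (ti in seq_along(tps)) {
    pk <- peaksets_by_time[[ti]]
    if (length(pk) == 0L) next
    hits <- GenomicRanges::findOverlaps(chains, pk)
    qh <- S4Vectors::queryHits(hits)
    present[unique(qh), ti] <- TRUE
    agg <- tapply(pk$read_count[S4Vectors::subjectHits(hits)], qh, sum)
    rc[as.integer(names(agg)), ti] <- as.numeric(agg)
  }
  pattern <- apply(present, 1, function(x) paste(as.integer(x),
                                                 collapse = ""))
  persistent <- rowSums(present) == length(tps)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(chains)),
                    start = bed_start(chains), end = bed_end(chains),
                    pattern = pattern, persistent = persistent,
                    stringsAsFactors = FALSE)
  colnames(rc) <- paste0("rc_", tps)
  out <- cbind(out, rc)
  list(chains = out, persistent_fraction = mean(persistent))
}

#' Log2 fold change of normalized read counts over union regions
#'
#' Comparison regions are the interval unions of overlapping peaks from
#' the two time points (a peak private to one time point forms its own
#' region). Read counts are normalized to counts per `scale` (counts per
#' million by default) and compared as
#' `log2((c2/N2 * scale + p) / (c1/N1 * scale + p))` with pseudocount `p`;
#' the original negative-binomial significance test is deliberately not
#' recomputed.
#'
#' @param peaks_t1,peaks_t2 peak `GRanges` (typically from
#'   [reproducible_peaks()]).
#' @param pseudocount pseudocount on the normalized scale (default 1).
#' @param scale normalization scale factor (default 1e6, i.e. CPM).
#' @return a data.frame: `chrom`, `start`, `end` (BED convention), `c1`,
#'   `c2` (raw summed counts), `log2fc`.
#' @export
union_region_fold_change <- function(peaks_t1, peaks_t2, pseudocount = 1,
                                     scale = 1e6) {
  n1 <- sum(peaks_t1$read_count); n2 <- sum(peaks_t2$read_count)
  stop_if(n1 <= 0 || n2 <= 0, "zero library size")
  regions <- GenomicRanges::reduce(suppressWarnings(c(
    GenomicRanges::granges(peaks_t1, use.mcols = FALSE),
    GenomicRanges::granges(peaks_t2, use.mcols = FALSE))))
  region_counts <- function(pk) {
    out <- rep(0, length(regions))
    if (length(pk) == 0L) return(out)
    hits <- GenomicRanges::findOverlaps(regions, pk)
    agg <- tapply(pk$read_count[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  }
  c1 <- region_counts(peaks_t1); c2 <- region_counts(peaks_t2)
  data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
             start = bed_start(regions), end = bed_end(regions),
             c1 = c1, c2 = c2,
             log2fc = log2((c2 / n2 * scale + pseudocount) /
                             (c1 / n1 * scale + pseudocount)),
             stringsAsFactors = FALSE)
}
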