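#' Parameters for the scripted ATAC peak-set simulator
#'
#' A catalog of disjoint promoter and intergenic sites is laid out on one
#' synthetic chromosome. At every time point each site is open with a
#' category- (or site-)specific probability; open sites emit a peak in each
#' donor unless lost to donor dropout. The default open-probability
#' schedules peak at the second time point and then decay — faster for
#' intergenic sites than for promoters — emulating the rapid decompaction /
#' slow recompaction regime of stimulated progenitors, and the default read
#' counts pass through a maximum at the second time point.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp (one
#'   synthetic chromosome by default).
#' @param n_promoters,n_intergenic_sites catalog sizes.
#' @param time_points ordered time labels.
#' @param open_probability_per_time per-time open probability: a vector
#'   (all sites), a `list(promoter=, intergenic=)` of vectors, or a full
#'   sites x times matrix (rows follow catalog order, promoters first).
#' @param readcount_mean_per_time expected read count of an emitted peak at
#'   each time point.
#' @param n_donors number of donors.
#' @param donor_dropout probability that a truly open site is missed in one
#'   donor at one time point.
#' @param promoter_width,intergenic_width site widths in bp.
#' @param seed integer RNG seed.
#' @return a list of class `peak_sim_params`.
#' @export
peak_sim_params <- function(chrom_lengths = c(chrS = 5e6),
                            n_promoters = 1000,
                            n_intergenic_sites = 800,
                            time_points = c("0h", "5h", "24h", "48h"),
                            open_probability_per_time =
                              list(promoter = c(0.80, 0.90, 0.80, 0.68),
                                   intergenic = c(0.55, 0.65, 0.45, 0.33)),
                            readcount_mean_per_time = c(60, 100, 70, 55),
                            n_donors = 3,
                            donor_dropout = 0.05,
                            promoter_width = 500,
                            intergenic_width = 300,
                            seed = 1L) {
  n_promoters <- assert_count(n_promoters, "n_promoters")
  n_intergenic_sites <- assert_count(n_intergenic_sites,
                                     "n_intergenic_sites",
                                     positive = FALSE)
  nt <- length(time_points)
  n_sites <- n_promoters + n_intergenic_sites
  op <- open_probability_per_time
  if (is.list(op) && !is.data.frame(op)) {
    stop_if(!all(c("promoter", "intergenic") %in% names(op)),
            "open-probability list needs `promoter` and `intergenic`")
    stop_if(length(op$promoter) != nt || length(op$intergenic) != nt,
            "open-probability vectors need one entry per time point")
    op <- rbind(matrix(op$promoter, n_promoters, nt, byrow = TRUE),
                matrix(op$intergenic, n_intergenic_sites, nt, byrow = TRUE))
  } else if (is.matrix(op)) {
    stop_if(nrow(op) != n_sites || ncol(op) != nt,
            "open-probability matrix must be sites x times")
  } else {
    stop_if(length(op) != nt,
            "open-probability vector needs one entry per time point")
    op <- matrix(op, n_sites, nt, byrow = TRUE)
  }
  assert_prob(as.numeric(op), "open_probability_per_time")
  stop_if(length(readcount_mean_per_time) != nt,
          "readcount_mean_per_time needs one entry per time point")
  assert_prob(donor_dropout, "donor_dropout")
  structure(list(chrom_lengths = chrom_lengths,
                 n_promoters = n_promoters,
                 n_intergenic_sites = n_intergenic_sites,
                 time_points = as.character(time_points),
                 open_probability = op,
                 readcount_mean_per_time = readcount_mean_per_time,
                 n_donors = assert_count(n_donors, "n_donors"),
                 donor_dropout = donor_dropout,
                 promoter_width = promoter_width,
                 intergenic_width = intergenic_width,
                 seed = as.integer(seed)),
            class = "peak_sim_params")
}

#' Simulate donor x time-point ATAC peak sets with known open/closed truth
#'
#' @param params a [peak_sim_params()] object.
#' @return a list of class `peak_sim` with elements
#'   * `sites`: `GRanges` site catalog (`site_id`, `category`, `gene_id`);
#'   * `annotation`: a [feature_annotation()] `GRanges` (promoters carrying
#'     gene ids, plus exon/intron/CpG/CTCF features that never touch the
#'     intergenic sites);
#'   * `peaksets`: named list (`"<donor>_<time>"`) of peak `GRanges`;
#'   * `truth$open`: sites x times logical matrix recorded before dropout;
#'   * `truth$emitted`: sites x times x donors logical array.
#' Every emitted peak coincides with exactly one catalog site; identical
#' seeds give bit-identical output.
#' @export
simulate_peaksets <- function(params) {
  stop_if(!inherits(params, "peak_sim_params"),
          "`params` must come from peak_sim_params()")
  p <- params
  set.seed(p$seed)
  tps <- p$time_points
  n_sites <- p$n_promoters + p$n_intergenic_sites
  chrom <- names(p$chrom_lengths)[1]

  ## Catalog layout: each site occupies a slot [site | flank]; promoter
  ## slots carry exon/intron features in the flank, intergenic flanks are
  ## feature-free so intergenic peaks stay annotation-free.
  category <- c(rep("promoter", p$n_promoters),
                rep("intergenic", p$n_intergenic_sites))
  width <- ifelse(category == "promoter",
                  p$promoter_width, p$intergenic_width)
  flank <- ifelse(category == "promoter",
                  p$promoter_width * 2L, p$intergenic_width * 2L)
  slot <- width + flank
  stop_if(sum(slot) > p$chrom_lengths[1],
          "chromosome too short for the requested site catalog")
  start0 <- cumsum(c(0, slot[-n_sites]))       # BED starts
  end0 <- start0 + width
  site_id <- sprintf("site%05d", seq_len(n_sites))
  gene_id <- ifelse(category == "promoter",
                    sprintf("gene%04d", seq_len(n_sites)), NA_character_)
  sites <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start0 + 1L, end0),
    site_id = site_id, category = category, gene_id = gene_id)
  GenomeInfoDb::seqlevels(sites) <- names(p$chrom_lengths)
  GenomeInfoDb::seqlengths(sites) <- p$chrom_lengths

  annotation <- build_annotation(sites, p)

  open <- matrix(stats::runif(n_sites * length(tps)) < p$open_probability,
                 n_sites, length(tps), dimnames = list(site_id, tps))
  emitted <- array(FALSE, c(n_sites, length(tps), p$n_donors),
                   dimnames = list(site_id, tps,
                                   paste0("donor", seq_len(p$n_donors))))
  peaksets <- list()
  for (d in seq_len(p$n_donors)) {
    donor <- paste0("donor", d)
    for (ti in seq_along(tps)) {
      keep <- open[, ti] &
        (stats::runif(n_sites) >= p$donor_dropout)
      emitted[, ti, d] <- keep
      idx <- which(keep)
      rc <- stats::rnbinom(length(idx),
                           mu = p$readcount_mean_per_time[ti], size = 10) + 1
      gr <- peak_set(chrom = rep(chrom, length(idx)),
                     start = start0[idx], end = end0[idx],
                     read_count = rc, donor = donor, time_point = tps[ti],
                     seqlengths = p$chrom_lengths)
      gr$site_id <- site_id[idx]
      peaksets[[paste0(donor, "_", tps[ti])]] <- gr
    }
  }
  structure(list(sites = sites, annotation = annotation,
                 peaksets = peaksets,
                 truth = list(open = open, emitted = emitted),
                 params = p),
            class = "peak_sim")
}

## Exon (then intron) directly downstream of each promoter; a CpG island
## inside ~30% of promoters; CTCF sites inside ~10% of promoter flanks.
build_annotation <- function(sites, p) {
  prom <- sites[sites$category == "promoter"]
  chrom <- as.character(GenomicRanges::seqnames(prom))
  ps <- bed_start(prom); pe <- bed_end(prom)
  exon_w <- round(p$promoter_width * 0.4)
  intron_w <- round(p$promoter_width * 0.8)
  ann <- list(
    feature_annotation(chrom, ps, pe, "promoter", prom$gene_id),
    feature_annotation(chrom, pe, pe + exon_w, "exon", prom$gene_id),
    feature_annotation(chrom, pe + exon_w, pe + exon_w + intron_w,
                       "intron", prom$gene_id))
  has_cpg <- stats::runif(length(prom)) < 0.3
  if (any(has_cpg))
    ann <- c(ann, list(feature_annotation(
      chrom[has_cpg], ps[has_cpg],
      ps[has_cpg] + round(p$promoter_width / 2), "CpG")))
  has_ctcf <- stats::runif(length(prom)) < 0.1
  if (any(has_ctcf))
    ann <- c(ann, list(feature_annotation(
      chrom[has_ctcf], pe[has_ctcf] + exon_w + intron_w,
      pe[has_ctcf] + exon_w + intron_w + 60, "CTCF")))
  out <- suppressWarnings(do.call(c, ann))
  GenomicRanges::sort(out)
}
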