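#' Simulate a scored TF-to-target regulatory network
#'
#' Draws a directed edge table in which a set of TF-coding genes (a subset
#' of the gene universe) regulates target genes with a confidence score in
#' `[0, 1]`, emulating a curated TF-promoter resource filtered downstream at
#' confidence > 0.5. A configurable fraction of targets is flagged
#' "coupled": callers should make the expression shift of a coupled target
#' copy its TF's shift (e.g. by spiking both in
#' [simulate_expression()]), giving ground truth for the
#' DE-TF-target enrichment analysis.
#'
#' @param n_tfs number of TF-coding genes.
#' @param n_targets number of target genes.
#' @param gene_universe character vector of all gene ids; TFs are taken
#'   from its head and targets sampled from the remainder. Default
#'   `sprintf("gene%04d", 1:(n_tfs+n_targets))`.
#' @param confidence_distribution edge confidence spec: either
#'   `list(kind = "constant", value = x)` or
#'   `list(kind = "uniform", min = a, max = b)`.
#' @param edges_per_target number of incoming TF edges drawn per target
#'   (recycled; each edge picks a TF uniformly, duplicates dropped).
#' @param coupled_fraction fraction of targets flagged as coupled to their
#'   first listed TF.
#' @param seed integer RNG seed.
#' @return a list of class `tf_network` with elements `edges` (data.frame:
#'   `tf`, `target`, `confidence`), `tf_universe` (character), and
#'   `coupling` (data.frame: `target`, `coupled_tf`, `coupled` flag).
#' @export
simulate_tf_network <- function(n_tfs, n_targets,
                                gene_universe = NULL,
                                confidence_distribution =
                                  list(kind = "uniform", min = 0, max = 1),
                                edges_per_target = 2,
                                coupled_fraction = 0.5,
                                seed = 1L) {
  n_tfs <- assert_count(n_tfs, "n_tfs")
  n_targets <- assert_count(n_targets, "n_targets")
  if (is.null(gene_universe))
    gene_universe <- sprintf("gene%04d", seq_len(n_tfs + n_targets))
  stop_if(n_tfs > length(gene_universe),
          "n_tfs exceeds the gene universe")
  stop_if(n_tfs + n_targets > length(gene_universe),
          "n_tfs + n_targets exceeds the gene universe")
  set.seed(as.integer(seed))
  tfs <- gene_universe[seq_len(n_tfs)]
  targets <- sample(setdiff(gene_universe, tfs), n_targets)
  k <- rep_len(edges_per_target, n_targets)
  edges <- data.frame(
    tf = unlist(lapply(seq_len(n_targets),
                       function(i) sample(tfs, k[i], replace = TRUE))),
    target = rep(targets, k), stringsAsFactors = FALSE)
  edges <- unique(edges)
  cd <- confidence_distribution
  edges$confidence <- switch(
    cd$kind,
    constant = rep(assert_prob(cd$value, "confidence value"), nrow(edges)),
    uniform = stats::runif(nrow(edges), cd$min, cd$max),
    stop("unknown confidence_distribution kind: ", cd$kind))
  assert_prob(edges$confidence, "confidence")
  first_tf <- edges$tf[match(targets, edges$target)]
  coupling <- data.frame(target = targets, coupled_tf = first_tf,
                         coupled = stats::runif(n_targets) <
                           coupled_fraction,
                         stringsAsFactors = FALSE)
  structure(list(edges = edges, tf_universe = tfs, coupling = coupling),
            class = "tf_network")
}

#' Simulate a binary single-cell accessibility incidence matrix
#'
#' Each peak of the catalog is included in each cell independently with a
#' per-peak probability, yielding the sparse binary cell x peak structure a
#' scATAC pipeline exports. The expected number of cells sharing a peak is
#' `n_cells * inclusion probability`.
#'
#' @param n_cells number of cells.
#' @param peak_catalog `GRanges` peak catalog (non-empty).
#' @param sharing_profile per-peak inclusion probability in `[0, 1]`
#'   (recycled over peaks).
#' @param seed integer RNG seed.
#' @return a list of class `cell_peak_incidence`: `incidence` (sparse
#'   `Matrix::dgCMatrix`, cells x peaks, 0/1), `peaks` (the catalog),
#'   `cells` (barcodes).
#' @export
simulate_scatac <- function(n_cells, peak_catalog, sharing_profile,
                            seed = 1L) {
  n_cells <- assert_count(n_cells, "n_cells")
  stop_if(length(peak_catalog) == 0L, "`peak_catalog` is empty")
  pr <- assert_prob(rep_len(sharing_profile, length(peak_catalog)),
                    "sharing_profile")
  set.seed(as.integer(seed))
  np <- length(peak_catalog)
  draws <- matrix(stats::runif(n_cells * np), n_cells, np) <
    rep(pr, each = n_cells)
  inc <- methods::as(Matrix::Matrix(draws * 1, sparse = TRUE), "CsparseMatrix")
  cells <- sprintf("bc%05d", seq_len(n_cells))
  rownames(inc) <- cells
  colnames(inc) <- if (!is.null(peak_catalog$site_id)) peak_catalog$site_id
                   else sprintf("peak%05d", seq_len(np))
  structure(list(incidence = inc, peaks = peak_catalog, cells = cells),
            class = "cell_peak_incidence")
}
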