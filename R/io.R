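#' Write a UMI matrix to disk
#'
#' Two layouts are supported: `"mtx"` writes a sparse Matrix-Market
#' triplet file `<basename>.mtx` with `<basename>.genes.txt` /
#' `<basename>.barcodes.txt` sidecars, `"tsv"` writes a dense
#' tab-delimited genes x cells table `<basename>.tsv`. Cell QC metadata,
#' when present, goes to `<basename>.meta.tsv`.
#'
#' @param x a [umi_matrix()].
#' @param dir output directory (created if needed).
#' @param basename file stem; default `"<donor>_<time_point>"`.
#' @param format `"mtx"` or `"tsv"`.
#' @return the paths written, invisibly.
#' @export
write_umi_matrix <- function(x, dir, basename = NULL,
                             format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stop_if(!inherits(x, "umi_matrix"), "`x` must be a umi_matrix")
  if (is.null(basename)) basename <- paste0(x$donor, "_", x$time_point)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, basename)
  paths <- character(0)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(x$counts),
                                               sparse = TRUE),
                                "CsparseMatrix"),
                    paste0(stem, ".mtx"))
    writeLines(x$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(x$cell_ids, paste0(stem, ".barcodes.txt"))
    paths <- paste0(stem, c(".mtx", ".genes.txt", ".barcodes.txt"))
  } else {
    utils::write.table(as.matrix(x$counts), paste0(stem, ".tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    paths <- paste0(stem, ".tsv")
  }
  if (!is.null(x$cell_meta)) {
    utils::write.table(x$cell_meta, paste0(stem, ".meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, paste0(stem, ".meta.tsv"))
  }
  invisible(paths)
}

#' Read a UMI matrix written by [write_umi_matrix()]
#'
#' @param stem path stem (without extension); `<stem>.mtx` + sidecars or
#'   `<stem>.tsv` must exist, with optional `<stem>.meta.tsv`.
#' @param donor,time_point labels for the returned object; defaults parsed
#'   from `basename(stem)` as `<donor>_<time>`.
#' @return a [umi_matrix()].
#' @export
read_umi_matrix <- function(stem, donor = NULL, time_point = NULL) {
  parts <- strsplit(basename(stem), "_")[[1]]
  if (is.null(donor)) donor <- parts[1]
  if (is.null(time_point) && length(parts) > 1) time_point <- parts[2]
  if (file.exists(paste0(stem, ".mtx"))) {
    counts <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
    gene_ids <- readLines(paste0(stem, ".genes.txt"))
    cell_ids <- readLines(paste0(stem, ".barcodes.txt"))
  } else if (file.exists(paste0(stem, ".tsv"))) {
    tab <- utils::read.table(paste0(stem, ".tsv"), sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE)
    counts <- as.matrix(tab)
    gene_ids <- rownames(tab); cell_ids <- colnames(tab)
  } else stop("no matrix found at stem: ", stem, call. = FALSE)
  meta_path <- paste0(stem, ".meta.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  storage.mode(counts) <- "integer"
  umi_matrix(counts, gene_ids, cell_ids, donor = donor,
             time_point = time_point %||% "t?", cell_meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write peaks as 6-column BED plus a read-count column
#'
#' Columns: chrom, start, end, name, score (= read count), strand (`.`),
#' read_count. Coordinates follow the BED convention.
#'
#' @param gr peak `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(gr, path) {
  rc <- if (is.null(gr$read_count)) rep(0, length(gr)) else gr$read_count
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = bed_start(gr), end = bed_end(gr),
                   name = sprintf("peak%05d", seq_along(gr)),
                   score = round(rc),
                   strand = ".",
                   read_count = rc)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED3/BED6, BED6+count, or narrowPeak files
#'
#' Read counts are taken from column 7 when present (our own BED6+count
#' layout and narrowPeak's signalValue), else from the BED score column,
#' else 0.
#'
#' @param path input file (plain text, tab-delimited, no header).
#' @param donor,time_point labels attached to the peaks.
#' @return a peak `GRanges`.
#' @export
read_peaks_bed <- function(path, donor = NA_character_,
                           time_point = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  rc <- if (ncol(tab) >= 7) tab[[7]] else if (ncol(tab) >= 5) tab[[5]] else 0
  peak_set(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
           read_count = rc, donor = donor, time_point = time_point)
}

#' Write / read a feature annotation table
#'
#' BED-like layout: chrom, start, end, category, gene_id.
#'
#' @param ann a [feature_annotation()] `GRanges`.
#' @param path file path.
#' @return `path` (writer, invisibly) or a `GRanges` (reader).
#' @export
write_annotation_bed <- function(ann, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ann)),
                   start = bed_start(ann), end = bed_end(ann),
                   category = ann$category,
                   gene_id = ifelse(is.na(ann$gene_id), ".", ann$gene_id))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  feature_annotation(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                     category = tab[[4]],
                     gene_id = ifelse(tab[[5]] == ".", NA_character_,
                                      tab[[5]]))
}

#' Read a three-column TF network edge table (tf, target, confidence)
#'
#' @param path tab-delimited file with a header line.
#' @return a list of class `tf_network` with an `edges` data.frame.
#' @export
read_network_tsv <- function(path) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  stop_if(!all(c("tf", "target", "confidence") %in% names(edges)),
          "network table needs columns tf, target, confidence")
  structure(list(edges = edges, tf_universe = unique(edges$tf)),
            class = "tf_network")
}

#' Read a two-column cell-to-cluster assignment table
#'
#' @param path tab-delimited file with a header line (cell_id, cluster).
#' @return a data.frame with columns `cell_id`, `cluster`.
#' @export
read_cluster_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stop_if(ncol(tab) < 2L, "cluster table needs two columns")
  names(tab)[1:2] <- c("cell_id", "cluster")
  tab
}

#' Write / read a binary cell x peak incidence matrix
#'
#' Matrix-Market triplet layout with `<stem>.barcodes.txt` and
#' `<stem>.peaks.bed` sidecars.
#'
#' @param x a `cell_peak_incidence`.
#' @param stem path stem.
#' @return paths written (writer, invisibly) or a `cell_peak_incidence`
#'   (reader). Fragment counts, if present in the file, are binarized at
#'   >= 1 on read.
#' @export
write_incidence_mtx <- function(x, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$incidence, paste0(stem, ".mtx"))
  writeLines(x$cells, paste0(stem, ".barcodes.txt"))
  write_peaks_bed(x$peaks, paste0(stem, ".peaks.bed"))
  invisible(paste0(stem, c(".mtx", ".barcodes.txt", ".peaks.bed")))
}

#' @rdname write_incidence_mtx
#' @export
read_incidence_mtx <- function(stem) {
  inc <- Matrix::readMM(paste0(stem, ".mtx"))
  if (methods::is(inc, "nMatrix")) inc <- inc * 1  # pattern file -> numeric
  inc <- methods::as(inc, "CsparseMatrix")
  inc@x[] <- as.numeric(inc@x >= 1)
  cells <- readLines(paste0(stem, ".barcodes.txt"))
  peaks <- read_peaks_bed(paste0(stem, ".peaks.bed"))
  rownames(inc) <- cells
  structure(list(incidence = inc, peaks = peaks, cells = cells),
            class = "cell_peak_incidence")
}

## key: value config files for the CLI ---------------------------------------
read_kv_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (!anyNA(num)) num else trimws(strsplit(v, ",")[[1]])
  })
  stats::setNames(vals, trimws(vapply(kv, `[[`, "", 1)))
}
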