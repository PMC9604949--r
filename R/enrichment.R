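#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on the margins, the p-value is the sum of hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (the probability-mass two-sided rule), with a
#' relative tolerance of 1e-7 absorbing floating-point ties. The odds
#' ratio is the sample ratio `(a*d)/(b*c)`; tables with a zero cell yield
#' `Inf` or `0` and are flagged.
#'
#' @param table a 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts `rbind(c(a, b), c(c, d))`.
#' @return a list: `p_value`, `odds_ratio`, `direction` (`"over"` if the
#'   observed `a` exceeds its expectation under independence, `"under"`
#'   if below, `"none"`), `degenerate` (zero-cell flag), `table`.
#' @export
fisher_two_sided <- function(table) {
  x <- as.vector(table)
  stop_if(length(x) != 4L, "need a 2x2 table")
  stop_if(any(x < 0) || any(x != round(x)),
          "counts must be non-negative integers")
  a <- x[1]; cc <- x[2]; b <- x[3]; d <- x[4]  # column-major
  m <- a + b          # row-1 total
  n <- cc + d         # row-2 total
  k <- a + cc         # column-1 total
  if (m + n == 0 || k == 0 || k == m + n) {
    p <- 1
  } else {
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- (a * d) / (b * cc)
  expected_a <- m * k / (m + n)
  direction <- if (m + n == 0 || a == expected_a) "none"
               else if (a > expected_a) "over" else "under"
  list(p_value = p, odds_ratio = or, direction = direction,
       degenerate = any(x == 0), table = matrix(x, 2))
}

#' Count DE and non-DE genes per promoter accessibility configuration
#'
#' Builds the 4 (configurations) x 2 (DE / non-DE) table over the shared
#' gene universe. A multi-promoter gene contributes to every configuration
#' class it belongs to, so column totals can exceed the number of genes.
#'
#' @param de_records a [call_de()] data.frame.
#' @param promoter_configs a [classify_promoter_configs()] data.frame (or
#'   already gene-level pairs from [gene_configs()]).
#' @return a list: `counts` (4x2 integer matrix, rows = configurations,
#'   columns = DE / non-DE), `gene_table` (gene_id, config, de), and
#'   `n_genes_in_universe`.
#' @export
config_by_de_table <- function(de_records, promoter_configs) {
  stop_if(nrow(de_records) == 0L, "empty gene universe")
  gc <- gene_configs(promoter_configs)
  gc <- gc[gc$gene_id %in% de_records$gene_id, , drop = FALSE]
  de_genes <- de_records$gene_id[de_records$de_flag != "none"]
  gc$de <- gc$gene_id %in% de_genes
  configs <- c("open-open", "open-closed", "closed-open", "closed-closed")
  counts <- matrix(0L, 4, 2, dimnames = list(configs, c("DE", "nonDE")))
  tab <- table(factor(gc$config, levels = configs),
               factor(gc$de, levels = c(TRUE, FALSE)))
  counts[, ] <- as.integer(tab)
  list(counts = counts, gene_table = gc,
       n_genes_in_universe = nrow(de_records))
}

#' Count genes per configuration x TF-status (the 8-group table)
#'
#' Crosses the four promoter accessibility configurations with the two
#' TF-status classes (`DE-TF-targeted` vs `nonDE-TF-targeted-only`) over
#' the targeted-gene universe; untargeted genes are excluded from the
#' table and reported separately. A multi-promoter gene contributes to
#' every configuration it belongs to, so the total of the 8 cells equals
#' the number of targeted genes counted with configuration multiplicity.
#'
#' @param de_records a [call_de()] data.frame.
#' @param tf_status result of [classify_tf_status()] computed on the same
#'   interval's DE calls.
#' @param promoter_configs a [classify_promoter_configs()] data.frame.
#' @return a list: `counts` (4x2 integer matrix, columns = DE-TF /
#'   nonDE-TF), `gene_table` (gene_id, config, tf_class, de),
#'   `n_untargeted`.
#' @export
eight_group_table <- function(de_records, tf_status, promoter_configs) {
  gcl <- tf_status$gene_class
  stop_if(!identical(sort(gcl$gene_id), sort(de_records$gene_id)),
          "TF status and DE records cover different gene universes")
  gc <- gene_configs(promoter_configs)
  gc <- gc[gc$gene_id %in% de_records$gene_id, , drop = FALSE]
  gc$tf_class <- gcl$class[match(gc$gene_id, gcl$gene_id)]
  n_untargeted <- sum(gc$tf_class == "untargeted")
  gc <- gc[gc$tf_class != "untargeted", , drop = FALSE]
  de_genes <- de_records$gene_id[de_records$de_flag != "none"]
  gc$de <- gc$gene_id %in% de_genes
  configs <- c("open-open", "open-closed", "closed-open", "closed-closed")
  tab <- table(factor(gc$config, levels = configs),
               factor(gc$tf_class,
                      levels = c("DE-TF-targeted", "nonDE-TF-targeted-only")))
  counts <- matrix(as.integer(tab), 4, 2,
                   dimnames = list(configs, c("DE-TF", "nonDE-TF")))
  list(counts = counts, gene_table = gc, n_untargeted = n_untargeted)
}

#' One-vs-rest enrichment contrasts over a grouped count matrix
#'
#' For every row (class) of a classes x 2 count matrix, tests the 2x2
#' table `[class vs rest] x [column-1 vs column-2]` with
#' [fisher_two_sided()]. This is the default contrast; any explicit 2x2
#' can be tested directly with [fisher_two_sided()].
#'
#' @param counts an integer matrix with exactly 2 columns (e.g. `counts`
#'   from [config_by_de_table()] or [eight_group_table()]).
#' @return a data.frame: `class`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `direction`.
#' @export
enrichment_contrasts <- function(counts) {
  stop_if(ncol(counts) != 2L, "`counts` must have 2 columns")
  res <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts[i, 1]; b <- counts[i, 2]
    cc <- sum(counts[-i, 1]); d <- sum(counts[-i, 2])
    ft <- fisher_two_sided(rbind(c(a, b), c(cc, d)))
    data.frame(class = rownames(counts)[i], a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               direction = ft$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
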