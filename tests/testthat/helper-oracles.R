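# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths (and, where possible, the base
# functions) used by the package itself.

## two-pass Pearson correlation between two vectors
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

## naive double-loop Ic: threshold-retained mean gene-gene over cell-cell r
ic_oracle <- function(m, threshold = 0.70) {
  gg <- c(); cc <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    r <- pearson_oracle(m[i, ], m[j, ])
    if (!is.na(r) && r > threshold) gg <- c(gg, r)
  }
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    r <- pearson_oracle(m[, i], m[, j])
    if (!is.na(r) && r > threshold) cc <- c(cc, r)
  }
  if (length(gg) == 0 || length(cc) == 0) return(NA_real_)
  mean(gg) / mean(cc)
}

## bp-resolution coverage of a BED-convention interval set on [0, L)
coverage_oracle <- function(start, end, L) {
  cov <- logical(L)
  for (k in seq_along(start)) cov[(start[k] + 1):end[k]] <- TRUE
  cov
}

## extract maximal TRUE runs of a coverage vector as BED intervals
runs_to_bed <- function(cov) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

## quadratic all-pairs >=1bp overlap test on BED intervals
overlaps_oracle <- function(s1, e1, s2, e2) {
  max(s1, s2) < min(e1, e2)
}

## full-enumeration two-sided Fisher p via exact log-choose probabilities
fisher_enum_oracle <- function(a, b, cc, d, tol = 1e-7) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  p <- exp(logp)
  min(1, sum(p[p <= exp(logp[support == a]) * (1 + tol)]))
}

## small deterministic umi_matrix builder
make_umi <- function(counts, donor = "donor1", time_point = "5h",
                     meta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  umi_matrix(counts,
             gene_ids = sprintf("g%d", seq_len(nrow(counts))),
             cell_ids = sprintf("c%d", seq_len(ncol(counts))),
             donor = donor, time_point = time_point, cell_meta = meta)
}

## metadata in which every cell passes QC
passing_meta <- function(n) {
  data.frame(cell_id = paste0("c", seq_len(n)),
             total_reads = rep(100000, n),
             mito_fraction = rep(0.05, n),
             ercc_pearson = rep(0.9, n))
}

## random BED peak table on one chromosome of length L
random_peaks <- function(n, L, seed, min_w = 50, max_w = 400) {
  set.seed(seed)
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample(0:(L - max_w - 1), n, replace = TRUE)
  data.frame(start = s, end = s + w)
}
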