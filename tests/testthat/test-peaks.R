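pk <- function(start, end, rc = 1, chrom = "chr1", donor = NA, tp = NA) {
  peak_set(rep(chrom, length(start)), start, end, rc, donor, tp)
}

test_that("reproducible_peaks is the bp-wise donor intersection", {
  ## worked example: [100,200) & [150,250) & [150,180) = [150,180)
  out <- reproducible_peaks(list(pk(100, 200), pk(150, 250), pk(150, 180)))
  expect_equal(bed_start(out), 150)
  expect_equal(bed_end(out), 180)
  expect_equal(out$read_count, 3)  # one contributing peak per donor

  ## identical sets -> identity; symmetric in donor order; idempotent
  a <- pk(c(0, 500), c(100, 800), rc = c(2, 5))
  same <- reproducible_peaks(list(a, a, a))
  expect_equal(bed_start(same), c(0, 500))
  expect_equal(bed_end(same), c(100, 800))
  expect_equal(same$read_count, c(6, 15))
  sets <- list(pk(c(0, 300), c(120, 400)), pk(60, 350), pk(c(20, 200), c(90, 380)))
  fwd <- reproducible_peaks(sets)
  rev <- reproducible_peaks(base::rev(sets))
  expect_equal(GenomicRanges::ranges(fwd), GenomicRanges::ranges(rev))
  again <- reproducible_peaks(list(fwd, fwd))
  expect_equal(GenomicRanges::ranges(again), GenomicRanges::ranges(fwd))

  ## a donor without peaks on a chromosome vetoes it
  two_chr <- list(
    peak_set(c("chr1", "chr2"), c(0, 0), c(100, 100)),
    peak_set("chr1", 10, 90))
  out2 <- reproducible_peaks(two_chr)
  expect_true(all(as.character(GenomicRanges::seqnames(out2)) == "chr1"))
  expect_warning(reproducible_peaks(list(pk(0, 10), pk(0, 10)[0])),
                 "empty")
})

test_that("reproducible_peaks equals the coverage oracle on random sets", {
  L <- 100000
  for (seed in 1:5) {
    sets <- lapply(1:3, function(d) {
      df <- random_peaks(40, L, seed * 10 + d)
      pk(df$start, df$end)
    })
    got <- reproducible_peaks(sets)
    covs <- lapply(sets, function(s)
      coverage_oracle(bed_start(s), bed_end(s), L))
    want <- runs_to_bed(Reduce(`&`, covs))
    expect_equal(bed_start(got), want$start)
    expect_equal(bed_end(got), want$end)
    ## coverage conservation
    expect_lte(sum(bed_end(got) - bed_start(got)),
               min(vapply(covs, sum, 1)))
  }
})

test_that("annotate_peaks assigns multi-category labels with exclusive intergenic", {
  ann <- feature_annotation(rep("chr1", 3), c(100, 200, 1000),
                            c(200, 300, 1100),
                            c("promoter", "exon", "CpG"),
                            c("gA", "gA", NA))
  ## spans promoter + first exon -> both categories
  res <- annotate_peaks(pk(c(150, 5000), c(250, 5100)), ann)
  expect_setequal(res$per_peak[[1]], c("promoter", "exon"))
  expect_equal(res$per_peak[[2]], "intergenic")
  expect_equal(unname(res$totals[c("promoter", "exon", "intergenic")]),
               c(1L, 1L, 1L))
  expect_error(annotate_peaks(peak_set("chrZ", 0, 10), ann), "chrZ")
})

test_that("annotate_peaks equals the quadratic overlap oracle", {
  set.seed(5)
  L <- 50000
  adf <- random_peaks(30, L, 77)
  cats <- sample(c("promoter", "exon", "intron", "CpG", "CTCF"), 30,
                 replace = TRUE)
  ann <- feature_annotation(rep("chr1", 30), adf$start, adf$end, cats,
                            ifelse(cats == "promoter", "g", NA))
  pdf <- random_peaks(50, L, 78)
  peaks <- pk(pdf$start, pdf$end)
  res <- annotate_peaks(peaks, ann)
  for (i in seq_len(50)) {
    want <- unique(cats[vapply(seq_len(30), function(j)
      overlaps_oracle(pdf$start[i], pdf$end[i], adf$start[j], adf$end[j]),
      logical(1))])
    if (length(want) == 0) want <- "intergenic"
    expect_setequal(res$per_peak[[i]], want)
  }
})

test_that("promoter calls and configurations recover scripted truth", {
  ann <- feature_annotation(rep("chr1", 4), c(0, 1000, 2000, 3000),
                            c(500, 1500, 2500, 3500),
                            rep("promoter", 4), paste0("g", 1:4))
  ## schedules: (1,1) (1,0) (0,1) (0,0)
  t1 <- pk(c(0, 1000), c(500, 1500))
  t2 <- pk(c(100, 2100), c(400, 2400))
  calls <- promoter_open_calls(list(a = t1, b = t2), ann)
  cfg <- classify_promoter_configs(calls, "a", "b")
  expect_equal(cfg$config,
               c("open-open", "open-closed", "closed-open",
                 "closed-closed"))
  ## the four classes partition the catalog
  expect_equal(nrow(cfg), 4L)
  ## no peaks at all -> everything closed
  empty <- promoter_open_calls(list(a = t1[0], b = t1[0]), ann)
  expect_false(any(empty$open))
  ## peak identical to the promoter interval -> open
  exact <- promoter_open_calls(list(a = pk(1000, 1500)), ann)
  expect_identical(unname(exact$open[, 1]), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("peak_trajectories links positions and reports presence patterns", {
  sets <- list(
    t1 = pk(c(0, 1000), c(100, 1100), rc = c(5, 7)),
    t2 = pk(c(10, 2000), c(90, 2100), rc = c(6, 9)),
    t3 = pk(0, 100, rc = 4),
    t4 = pk(20, 80, rc = 2))
  tr <- peak_trajectories(sets)
  ch <- tr$chains[order(tr$chains$start), ]
  expect_equal(ch$pattern, c("1111", "1000", "0100"))
  expect_equal(ch$persistent, c(TRUE, FALSE, FALSE))
  expect_equal(ch$rc_t1, c(5, 7, 0))
  expect_equal(ch$rc_t2, c(6, 0, 9))
  expect_equal(tr$persistent_fraction, 1 / 3)
})

test_that("peak_trajectories equals a coverage-component oracle", {
  L <- 100000
  sets <- lapply(1:4, function(ti) {
    df <- random_peaks(25, L, 900 + ti)
    pk(df$start, df$end, rc = ti)
  })
  names(sets) <- paste0("t", 1:4)
  tr <- peak_trajectories(sets)
  pool_cov <- Reduce(`|`, lapply(sets, function(s)
    coverage_oracle(bed_start(s), bed_end(s), L)))
  chains <- runs_to_bed(pool_cov)
  expect_equal(sort(tr$chains$start), sort(chains$start))
  ## per-chain presence recomputed bp-wise
  for (k in seq_len(nrow(chains))) {
    idx <- which(tr$chains$start == chains$start[k])
    want <- vapply(sets, function(s)
      any(bed_start(s) < chains$end[k] & bed_end(s) > chains$start[k]),
      logical(1))
    expect_equal(unname(strsplit(tr$chains$pattern[idx], "")[[1]] == "1"),
                 unname(want))
  }
})

test_that("union_region_fold_change follows the normalized formula", {
  ## identical peaks and libraries -> 0 everywhere
  a <- pk(c(0, 1000), c(100, 1100), rc = c(10, 30))
  fc0 <- union_region_fold_change(a, a)
  expect_true(all(fc0$log2fc == 0))

  ## normalized counts 1 vs 4 with vanishing pseudocount -> log2fc = 2
  t1 <- pk(c(0, 10000), c(100, 10100), rc = c(1, 999999))
  t2 <- pk(c(0, 10000), c(100, 10100), rc = c(4, 999996))
  fc <- union_region_fold_change(t1, t2, pseudocount = 1e-9)
  expect_equal(fc$log2fc[1], 2, tolerance = 1e-6)

  ## region private to t2: positive, bounded by the pseudocount formula
  t2b <- pk(c(0, 10000, 20000), c(100, 10100, 20100), rc = c(1, 999998, 1))
  fcb <- union_region_fold_change(t1, t2b)
  private <- fcb[fcb$start == 20000, ]
  expect_gt(private$log2fc, 0)
  expect_equal(private$log2fc, log2((1 / 1e6 * 1e6 + 1) / 1))
  expect_error(union_region_fold_change(pk(0, 1, rc = 0), a), "library")
})
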