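test_that("simulate_expression honours degenerate activity profiles", {
  base <- function(p, leak = 0) expression_sim_params(
    n_genes = 40, n_cells_per_time = 30, time_points = c("5h", "24h"),
    p_active_per_time = c(p, p), burst_mean = 5, dispersion = 2,
    n_donors = 1, donor_effect_sd = 0, cell_size_sd = 0,
    leakage = leak, seed = 11)
  allzero <- simulate_expression(base(0))
  for (m in allzero$matrices) expect_true(all(m$counts == 0))

  ## p_active = 1, leakage 0: detection prob per gene is 1 - P(NB = 0)
  sim <- simulate_expression(base(1))
  p0 <- (2 / (2 + 5))^2                      # NB zero mass, mu=5 size=2
  expected <- 40 * (1 - p0)
  for (m in sim$matrices) {
    gpc <- genes_per_cell_summary(m)
    tol <- 3 * sqrt(40 * (1 - p0) * p0 / 30)  # 3 SDs of the mean
    expect_lt(abs(gpc$mean - expected), tol)
  }
})

test_that("simulate_expression is deterministic and truth-consistent", {
  p <- expression_sim_params(n_genes = 30, n_cells_per_time = 20,
                             time_points = c("5h", "24h", "48h"),
                             p_active_per_time = c(0.2, 0.6, 0.4),
                             n_donors = 2, seed = 42)
  a <- simulate_expression(p)
  b <- simulate_expression(p)
  expect_identical(lapply(a$matrices, `[[`, "counts"),
                   lapply(b$matrices, `[[`, "counts"))
  ## conservation: "off" cells only ever carry the 1-UMI leakage
  for (k in names(a$matrices)) {
    off <- !a$truth$on[[k]]
    expect_true(all(a$matrices[[k]]$counts[off] <= 1))
  }
})

test_that("simulate_expression default profile rises then falls", {
  sim <- simulate_expression(expression_sim_params(
    n_genes = 300, n_cells_per_time = 120, n_donors = 1, seed = 5))
  means <- vapply(sim$matrices,
                  function(m) genes_per_cell_summary(m)$mean, 1)
  expect_lt(means[1], means[2])              # 5h -> 24h rise
  expect_gt(max(means), means[length(means)])  # decay after the plateau
})

test_that("simulate_expression rejects invalid parameters", {
  expect_error(expression_sim_params(n_genes = 0), "positive")
  expect_error(expression_sim_params(time_points = c("5h", "5h")),
               "unique")
  expect_error(expression_sim_params(p_active_per_time = c(0.5, 2),
                                     time_points = c("a", "b")),
               "\\[0, 1\\]")
})

test_that("simulate_peaksets trivial regimes and truth bookkeeping", {
  p1 <- peak_sim_params(n_promoters = 30, n_intergenic_sites = 20,
                        chrom_lengths = c(chrS = 2e5),
                        open_probability_per_time = rep(1, 4),
                        donor_dropout = 0, n_donors = 2, seed = 1)
  sim1 <- simulate_peaksets(p1)
  for (ps in sim1$peaksets) expect_length(ps, 50)
  expect_true(all(sim1$truth$open))

  ## scripted schedule recorded in the pre-dropout truth
  p2 <- peak_sim_params(n_promoters = 10, n_intergenic_sites = 5,
                        chrom_lengths = c(chrS = 1e5),
                        open_probability_per_time = c(1, 1, 0, 0),
                        donor_dropout = 0.5, n_donors = 2, seed = 2)
  sim2 <- simulate_peaksets(p2)
  expect_true(all(sim2$truth$open[, 1:2]))
  expect_false(any(sim2$truth$open[, 3:4]))
})

test_that("simulate_peaksets emitted counts match the binomial expectation", {
  p <- peak_sim_params(n_promoters = 600, n_intergenic_sites = 400,
                       chrom_lengths = c(chrS = 3e6),
                       open_probability_per_time = rep(0.6, 4),
                       donor_dropout = 0.2, n_donors = 3, seed = 7)
  sim <- simulate_peaksets(p)
  expected <- 1000 * 0.6 * 0.8
  tol <- 3 * sqrt(1000 * 0.48 * 0.52)
  for (ps in sim$peaksets) expect_lt(abs(length(ps) - expected), tol)
  ## every emitted peak overlaps exactly one catalog site
  hits <- GenomicRanges::countOverlaps(sim$peaksets[[1]], sim$sites)
  expect_true(all(hits == 1))
  ## catalog sites are pairwise disjoint
  expect_equal(sum(GenomicRanges::countOverlaps(sim$sites, sim$sites)),
               length(sim$sites))
})

test_that("simulate_tf_network confidence filtering behaves as specified", {
  const <- function(v) list(kind = "constant", value = v)
  hi <- simulate_tf_network(5, 50, confidence_distribution = const(1),
                            seed = 1)
  expect_true(all(hi$edges$confidence > 0.5))
  lo <- simulate_tf_network(5, 50, confidence_distribution = const(0.4),
                            seed = 1)
  expect_equal(sum(lo$edges$confidence > 0.5), 0)

  unif <- simulate_tf_network(50, 10000, edges_per_target = 1,
                              confidence_distribution =
                                list(kind = "uniform", min = 0, max = 1),
                              seed = 3)
  frac <- mean(unif$edges$confidence > 0.5)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(unif$edges)))
  expect_error(simulate_tf_network(10, 5,
                                   gene_universe = paste0("g", 1:8)),
               "universe")
})

test_that("simulate_scatac matches its inclusion probabilities", {
  catalog <- peak_set(rep("chr1", 4), c(0, 100, 200, 300) * 10,
                      c(50, 150, 250, 350) * 10)
  all_in <- simulate_scatac(20, catalog, 1, seed = 1)
  expect_true(all(Matrix::colSums(all_in$incidence) == 20))
  none <- simulate_scatac(20, catalog, 0, seed = 1)
  expect_equal(sum(none$incidence), 0)
  expect_error(simulate_scatac(10, catalog[0], 0.5), "empty")

  ## the paper-scale sharing regime: 5,000 cells, p = 0.024 -> ~120 cells
  one <- peak_set("chr1", 0, 500)
  inc <- simulate_scatac(5000, one, 0.024, seed = 9)
  expect_lt(abs(sum(inc$incidence) - 120), 3 * sqrt(5000 * 0.024 * 0.976))
})
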