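test_that("zscore reproduces the stated formula on hand-built matrices", {
  ## t1 cells per gene: mean 1, sample sd 1; t2: mean 3, sample sd 2
  t1 <- make_umi(rbind(c(0, 1, 2), c(5, 5, 5)), time_point = "5h")
  t2 <- make_umi(rbind(c(1, 3, 5), c(5, 5, 5)), time_point = "24h")
  z <- zscore(t1, t2)
  expect_equal(z$z[1], 2 / sqrt(5))
  expect_equal(z$z[2], 0)                 # equal means, zero sds -> 0
  expect_true(z$zero_denominator[2])

  ## antisymmetry is exact
  zr <- zscore(t2, t1)
  expect_identical(z$z, -zr$z)

  ## zero denominator with differing means -> signed sentinel, flagged
  t3 <- make_umi(rbind(c(9, 9, 9), c(1, 1, 1)), time_point = "24h")
  zs <- zscore(t1, t3)
  expect_equal(zs$z[2], -12)
  expect_true(zs$zero_denominator[2])
})

test_that("zscore ignores cell order and validates inputs", {
  set.seed(4)
  a <- matrix(rpois(50, 5), 5, 10)
  b <- matrix(rpois(50, 8), 5, 10)
  z1 <- zscore(make_umi(a), make_umi(b))
  z2 <- zscore(make_umi(a[, sample(10)]), make_umi(b[, sample(10)]))
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
  expect_error(zscore(make_umi(a), make_umi(b[1:4, ])), "gene universe")
  expect_error(zscore(make_umi(a[, 1, drop = FALSE]), make_umi(b)),
               "2 cells")
})

test_that("call_de averages donors and applies inclusive thresholds", {
  zd <- function(z) data.frame(gene_id = paste0("g", seq_along(z)), z = z,
                               zero_denominator = FALSE)
  ## opposing donors cancel
  de <- call_de(list(zd(c(3, 2, -2)), zd(c(-3, 2, -2))))
  expect_equal(de$mean_z, c(0, 2, -2))
  expect_equal(as.character(de$de_flag), c("none", "up", "down"))
  ## single donor at the boundary: inclusive
  de1 <- call_de(zd(c(2, 1.999, -2)))
  expect_equal(as.character(de1$de_flag), c("up", "none", "down"))
  ## identical donors: mean equals the per-donor value
  de2 <- call_de(list(zd(c(1.5, 0)), zd(c(1.5, 0))))
  expect_equal(de2$mean_z, de2$z_1)
  expect_error(call_de(list(zd(1:2), data.frame(gene_id = "x", z = 1))),
               "universe")
})

test_that("classify_tf_status partitions genes by surviving DE-TF edges", {
  de <- data.frame(gene_id = c("tf1", "tf2", "a", "b", "c", "d"),
                   mean_z = c(3, 0, 0, 0, 0, 0),
                   de_flag = c("up", "none", rep("none", 4)))
  edges <- data.frame(tf = c("tf1", "tf2", "tf1", "tf2"),
                      target = c("a", "b", "c", "c"),
                      confidence = c(0.51, 0.9, 0.5, 0.8))
  cls <- classify_tf_status(de, edges)
  got <- setNames(cls$gene_class$class, cls$gene_class$gene_id)
  expect_equal(got[["a"]], "DE-TF-targeted")        # conf 0.51 from DE TF
  expect_equal(got[["b"]], "nonDE-TF-targeted-only")
  ## c: the 0.5 edge from the DE TF is dropped (strict filter); only the
  ## non-DE tf2 edge survives
  expect_equal(got[["c"]], "nonDE-TF-targeted-only")
  expect_equal(got[["d"]], "untargeted")
  ## partition: exhaustive and exclusive over the DE-record universe
  expect_setequal(cls$gene_class$gene_id, de$gene_id)
  expect_equal(anyDuplicated(cls$gene_class$gene_id), 0L)

  ## TF absent from the universe: warn, keep the edge, treat as non-DE
  edges2 <- rbind(edges, data.frame(tf = "ghost", target = "d",
                                    confidence = 0.9))
  expect_warning(cls2 <- classify_tf_status(de, edges2), "absent")
  got2 <- setNames(cls2$gene_class$class, cls2$gene_class$gene_id)
  expect_equal(got2[["d"]], "nonDE-TF-targeted-only")
})

test_that("spiked synthetic targets concentrate in the DE-TF-targeted class", {
  ## TFs and coupled targets spiked together; uncoupled targets unspiked
  net <- simulate_tf_network(10, 120, edges_per_target = 1,
                             gene_universe = sprintf("gene%04d", 1:500),
                             confidence_distribution =
                               list(kind = "constant", value = 0.9),
                             coupled_fraction = 0.5, seed = 8)
  de_tfs <- net$tf_universe[1:5]
  coupled <- net$coupling$target[net$coupling$coupled &
                                   net$coupling$coupled_tf %in% de_tfs]
  spike_idx <- match(unique(c(de_tfs, coupled)),
                     sprintf("gene%04d", 1:500))
  ep <- expression_sim_params(
    n_genes = 500, n_cells_per_time = 100,
    time_points = c("5h", "24h"), p_active_per_time = c(1, 1),
    burst_mean = 10, dispersion = 20, cell_size_sd = 0.15,
    n_donors = 2, donor_effect_sd = 0.05,
    spike = list(genes = spike_idx, time_points = "24h", fc = 4),
    seed = 13)
  sim <- simulate_expression(ep)
  de <- call_de(lapply(1:2, function(d)
    zscore(sim$matrices[[paste0("donor", d, "_5h")]],
           sim$matrices[[paste0("donor", d, "_24h")]])))
  cls <- classify_tf_status(de, net)
  tab <- table(coupled = net$coupling$target %in% coupled,
               de_tf = net$coupling$target %in%
                 cls$gene_class$gene_id[cls$gene_class$class ==
                                          "DE-TF-targeted"])
  ft <- fisher_two_sided(matrix(as.integer(tab)[c(4, 2, 3, 1)], 2))
  expect_lt(ft$p_value, 0.01)
})
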