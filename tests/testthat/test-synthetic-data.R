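test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_config(seed = 71)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$loops, g2$loops)
  c1 <- generate_cohort(g1, 1)
  c2 <- generate_cohort(g2, 1)
  expect_identical(unclass(c1$expr), unclass(c2$expr))
  expect_identical(c1$meth$beta, c2$meth$beta)
  sc1 <- generate_single_cell(g1)
  sc2 <- generate_single_cell(g2)
  expect_identical(as.matrix(sc1$counts), as.matrix(sc2$counts))
  # a different seed changes values but not the truth-structure dimensions
  g3 <- generate_genome(small_config(seed = 72))
  expect_equal(table(g3$truth$lnc_cluster), table(g1$truth$lnc_cluster))
  expect_false(identical(unclass(generate_cohort(g3, 1)$expr),
                         unclass(c1$expr)))
})

test_that("planted loops join the enhancer CpG and the target TSS exactly", {
  g <- generate_genome(small_config(seed = 73))
  expect_true(audit_truth(g))
  geom <- g$reg_pair_geometry
  ann <- g$annotation
  loops <- g$loops
  for (i in seq_len(nrow(geom))) {
    tss <- ann$tss[ann$gene_id == geom$lnc_id[i]]
    in1 <- loops$chrom1 == geom$chrom[i] &
      loops$start1 <= geom$pos[i] & geom$pos[i] < loops$end1
    in2 <- loops$chrom2 == geom$chrom[i] & loops$start2 <= tss & tss < loops$end2
    expect_equal(any(in1 & in2), geom$looped[i])
  }
  # decoy loops touch neither CpGs nor TSSs
  decoys <- loops[startsWith(loops$loop_id, "decoy"), ]
  feats <- c(g$cpg_positions$pos, ann$tss)
  fchr <- c(g$cpg_positions$chrom, ann$chrom)
  for (j in seq_len(nrow(decoys))) {
    hit <- (fchr == decoys$chrom1[j] & feats >= decoys$start1[j] &
              feats < decoys$end1[j]) |
      (fchr == decoys$chrom2[j] & feats >= decoys$start2[j] &
         feats < decoys$end2[j])
    expect_false(any(hit))
  }
})

test_that("zero planted enhancer pairs yields empty truth but decoy loops", {
  g <- generate_genome(small_config(seed = 74, n_enhancer_pairs = 0))
  expect_equal(nrow(g$truth$reg_pairs), 0L)
  expect_gt(nrow(g$loops), 0L)
  expect_true(all(startsWith(g$loops$loop_id, "decoy")))
})

test_that("the noiseless limit gives perfect within-block correlation", {
  cfg <- small_config(seed = 75, noise_sd = 1e-9,
                      frac_low_expressed = 0, frac_low_variance = 0)
  g <- generate_genome(cfg)
  co <- generate_cohort(g, 1)
  lg <- log2(unclass(co$expr) + 1)
  tr <- g$truth
  c1 <- names(tr$lnc_cluster)[tr$lnc_cluster == "1"][1:4]
  a1 <- names(tr$mrna_cluster)[tr$mrna_cluster == "A"][2:5]
  rho <- stats::cor(t(lg[c1, ]), t(lg[a1, ]), method = "spearman")
  expect_true(all(rho > 0.999))
})

test_that("an all-ER-positive cohort propagates to a contract error downstream", {
  cfg <- small_config(seed = 76, er_pos_fraction = 1)
  g <- generate_genome(cfg)
  co <- generate_cohort(g, 1)
  expect_true(all(co$clinical$er_status == "pos"))
  prep <- prep_expression(co$expr)
  expect_error(moderated_t_de(prep$expr, co$clinical$er_status, group1 = "pos"),
               "two groups")
})

test_that("within-block correlation exceeds between-block correlation", {
  g <- generate_genome(small_config(seed = 77))
  co <- generate_cohort(g, 1)
  lg <- log2(unclass(co$expr) + 1)
  tr <- g$truth
  mean_rho <- function(lset, mset)
    mean(stats::cor(t(lg[lset, ]), t(lg[mset, ]), method = "spearman"))
  c1 <- names(tr$lnc_cluster)[tr$lnc_cluster == "1"]
  c2 <- names(tr$lnc_cluster)[tr$lnc_cluster == "2"]
  A <- names(tr$mrna_cluster)[tr$mrna_cluster == "A"]
  B <- names(tr$mrna_cluster)[tr$mrna_cluster == "B"]
  expect_gt(mean_rho(c1, A), abs(mean_rho(c1, B)) + 0.2)
  expect_gt(mean_rho(c2, B), abs(mean_rho(c2, A)) + 0.2)
})

test_that("survival generation follows the exponential planted-hazard model", {
  # no planted hazards: event times independent of every gene
  cfg <- small_config(seed = 78, n_prognostic = 0)
  g <- generate_genome(cfg)
  cors <- replicate(20, {
    co <- generate_survival(generate_cohort(g, 1), g)
    x <- log2(unclass(co$expr)[1, ] + 1)
    suppressWarnings(stats::cor(x, co$clinical$os_time, method = "spearman"))
  })
  expect_lt(abs(mean(cors)), 0.08)

  # doubling the baseline hazard halves the median event time
  co <- generate_cohort(g, 1)
  t1 <- generate_survival(co, g, baseline_hazard = 1e-4,
                          censor_hazard = 1e-9)$clinical$os_time
  t2 <- generate_survival(co, g, baseline_hazard = 2e-4,
                          censor_hazard = 1e-9)$clinical$os_time
  expect_equal(stats::median(t2) / stats::median(t1), 0.5, tolerance = 0.35)
  # event rate at defaults sits in the plausible clinical range
  ev <- generate_survival(co, g)$clinical$os_event
  expect_gt(mean(ev), 0.2)
  expect_lt(mean(ev), 0.8)
  expect_error(generate_survival(co, g, baseline_hazard = 0), "positive")
})

test_that("single-cell counts follow the planted cell-type structure", {
  g <- generate_genome(small_config(seed = 79))
  sc <- generate_single_cell(g)
  norm <- sc_lognormalize(sc)
  tr <- g$truth
  c2genes <- names(tr$lnc_cluster)[tr$lnc_cluster == "2"]
  caf <- names(norm$cell_type)[norm$cell_type == "CAF"]
  cancer <- names(norm$cell_type)[norm$cell_type == "cancer_epithelial"]
  m_caf <- mean(norm$norm[c2genes, caf])
  m_can <- mean(norm$norm[c2genes, cancer])
  expect_gt(m_caf, m_can)

  # full dropout produces an all-zero matrix
  g0 <- generate_genome(small_config(seed = 79, sc_dropout = 1))
  sc0 <- generate_single_cell(g0)
  expect_equal(sum(sc0$counts), 0)
  expect_error(generate_single_cell(g, n_cells_per_type = 0), ">= 1")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(er_pos_fraction = 0), "er_pos_fraction")
  expect_error(sim_config(lnc_cluster_sizes = c(500, 200, 100), n_lnc = 600),
               "exceed")
  expect_error(sim_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(generate_cohort(list(), 1), "generate the genome")
  expect_error(generate_cohort(generate_genome(small_config()), 3), "1 or 2")
  expect_error(generate_genome(sim_config(chrom_length = 1e5)),
               "chrom_length")
})
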