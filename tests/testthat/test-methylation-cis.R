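mk_meth <- function(beta, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(nrow(beta)) * 1000L
  methylation_matrix(beta, data.frame(cpg_id = rownames(beta),
                                      chrom = chrom, pos = pos))
}

test_that("methylation preprocessing filters, imputes, and trims by IQR", {
  set.seed(61)
  n <- 20
  beta <- matrix(stats::runif(12 * n), 12, n,
                 dimnames = list(paste0("c", 1:12), paste0("s", 1:n)))
  beta["c1", 1:12] <- NA                # 60 % missing -> dropped
  beta["c2", 1] <- NA                   # one missing value -> imputed
  beta["c3", ] <- 0.5                   # constant -> IQR filter removes
  m <- mk_meth(beta)
  res <- preprocess_methylation(m, max_missing = 0.5, knn_k = 3, iqr_min = 0.1)
  expect_false("c1" %in% rownames(res$beta))
  expect_false("c3" %in% rownames(res$beta))
  expect_true(all(!is.na(res$beta)))
  expect_true(all(res$beta >= 0 & res$beta <= 1))

  # neighbors all carrying 0.5 at the missing sample impute exactly 0.5
  beta2 <- matrix(stats::runif(8 * n, 0.2, 0.8), 8, n,
                  dimnames = list(paste0("c", 1:8), paste0("s", 1:n)))
  target <- beta2["c1", -1]
  for (k in 2:4) beta2[paste0("c", k), ] <- c(0.5, target + 0.001 * k)
  beta2["c1", 1] <- NA
  res2 <- preprocess_methylation(mk_meth(beta2), knn_k = 3, iqr_min = 0)
  expect_equal(res2$beta["c1", 1], 0.5, tolerance = 1e-12)

  expect_error(preprocess_methylation(mk_meth(beta), knn_k = 50), "fewer than")
})

test_that("cis correlation restricts to chromosomes and replicates the oracle", {
  set.seed(62)
  n <- 30
  sample_ids <- paste0("s", 1:n)
  expr_base <- matrix(stats::runif(3 * n, 1, 6), 3, n,
                      dimnames = list(c("L1", "L2", "L3"), sample_ids))
  lnc <- expression_matrix(expr_base, "log2p1")
  # 4 CpGs x 2 chromosomes; c1 is a noise-free inverse copy of L1
  beta <- matrix(stats::runif(4 * n, 0.1, 0.9), 4, n,
                 dimnames = list(paste0("c", 1:4), sample_ids))
  beta["c1", ] <- 1 - (expr_base["L1", ] - 1) / 6
  meth <- mk_meth(beta, chrom = c("chr1", "chr1", "chr2", "chr2"),
                  pos = c(100000L, 200000L, 100000L, 200000L))
  ann <- gene_annotation(data.frame(
    gene_id = c("L1", "L2", "L3"), chrom = c("chr1", "chr2", "chr3"),
    start = c(1000L, 1000L, 1000L), end = c(2000L, 2000L, 2000L),
    strand = "+", biotype = "lncRNA"))
  res <- cis_correlation(meth, lnc, meth, lnc, ann, alpha = 0.05)
  # same-chromosome grid: c1,c2 x L1 and c3,c4 x L2 -> 4 tests, never chr3
  expect_equal(res$n_tests, 4L)
  expect_false(any(res$pairs$lnc_id == "L3"))
  # the noise-free pair has rho -1 in both cohorts and is kept
  expect_true(any(res$pairs$cpg_id == "c1" & res$pairs$lnc_id == "L1"))
  kept <- res$pairs[res$pairs$cpg_id == "c1", ]
  expect_equal(kept$rho_A, -1)
  expect_equal(kept$distance_bp, abs(100000L - 1000L))

  # double-loop oracle with the identical Bonferroni m
  manual_kept <- character()
  for (cg in rownames(beta)) for (ln in c("L1", "L2")) {
    cchr <- c(c1 = "chr1", c2 = "chr1", c3 = "chr2", c4 = "chr2")[cg]
    lchr <- c(L1 = "chr1", L2 = "chr2")[ln]
    if (cchr != lchr) next
    ct <- suppressWarnings(stats::cor.test(beta[cg, ], expr_base[ln, ],
                                           method = "spearman"))
    rho <- unname(ct$estimate)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    if (p * 4 < 0.05 && rho < 0) manual_kept <- c(manual_kept, paste(cg, ln))
  }
  expect_setequal(paste(res$pairs$cpg_id, res$pairs$lnc_id), manual_kept)

  ann_off <- ann; ann_off$chrom <- "chrX"
  expect_error(cis_correlation(meth, lnc, meth, lnc,
                               gene_annotation(as.data.frame(ann_off))),
               "zero same-chromosome|no chromosome")
})

test_that("CpG state enrichment counts equal a point-in-interval scan", {
  pos <- data.frame(cpg_id = paste0("c", 1:50), chrom = "chr1",
                    pos = seq(500L, by = 1000L, length.out = 50))
  segs <- rbind(genomic_intervals("chr1", 0L, 10000L, "EhAct"),
                genomic_intervals("chr1", 10000L, 50000L, "QsLow"))
  track <- segmentation_track("x", segs)
  res <- cpg_context_enrichment(paste0("c", 1:10), pos, track, pos$cpg_id)
  expect_equal(res$overlap_count[res$term_id == "EhAct"], 10L)
  manual <- sum(pos$pos[1:10] >= 0 & pos$pos[1:10] < 10000)
  expect_equal(res$overlap_count[res$term_id == "EhAct"], manual)
  expect_lt(res$p[res$term_id == "EhAct"], 1e-5)

  res_all <- cpg_context_enrichment(pos$cpg_id, pos, track, pos$cpg_id)
  expect_true(all(res_all$p == 1))
  expect_error(cpg_context_enrichment("c1", pos, track, c(pos$cpg_id, "zz")),
               "without position")
})

test_that("loop support requires the two features in different feet", {
  loops <- loop_set(data.frame(
    chrom1 = "chr1", start1 = 1000L, end1 = 2000L,
    chrom2 = "chr1", start2 = 50000L, end2 = 51000L))
  pos <- data.frame(cpg_id = c("cA", "cB"), chrom = "chr1",
                    pos = c(1500L, 50500L))
  ann <- gene_annotation(data.frame(
    gene_id = c("L1", "L2"), chrom = "chr1",
    start = c(50400L, 1200L), end = c(50900L, 1900L),
    strand = "+", biotype = "lncRNA"))
  pairs <- data.frame(cpg_id = c("cA", "cA", "cB"),
                      lnc_id = c("L1", "L2", "L1"))
  res <- loop_support(pairs, pos, loops, ann)
  expect_true(res$loop_supported[1])    # CpG foot1, TSS foot2
  expect_false(res$loop_supported[2])   # both in foot1
  expect_false(res$loop_supported[3])   # both in foot2

  # random loops + pairs against an exhaustive double loop
  set.seed(63)
  nl <- 50
  base <- sample.int(1e6, nl)
  loops_r <- loop_set(data.frame(
    chrom1 = sample(c("chr1", "chr2"), nl, TRUE), start1 = base,
    end1 = base + 800L, chrom2 = "chr1",
    start2 = base + 20000L, end2 = base + 21000L))
  posr <- data.frame(cpg_id = paste0("c", 1:20), chrom = "chr1",
                     pos = sample.int(1.1e6, 20))
  gstart <- sample.int(1.1e6, 20)
  annr <- gene_annotation(data.frame(
    gene_id = paste0("L", 1:20), chrom = "chr1",
    start = gstart, end = gstart + 500L, strand = "+", biotype = "lncRNA"))
  pairs_r <- data.frame(cpg_id = posr$cpg_id, lnc_id = annr$gene_id)
  got <- loop_support(pairs_r, posr, loops_r, annr)
  inside <- function(chr, p, fc, fs, fe) chr == fc & p >= fs & p < fe
  for (i in seq_len(nrow(pairs_r))) {
    tssi <- annr$tss[i]
    want <- FALSE
    for (j in seq_len(nl)) {
      a1 <- inside("chr1", posr$pos[i], loops_r$chrom1[j], loops_r$start1[j], loops_r$end1[j])
      a2 <- inside("chr1", posr$pos[i], loops_r$chrom2[j], loops_r$start2[j], loops_r$end2[j])
      b1 <- inside("chr1", tssi, loops_r$chrom1[j], loops_r$start1[j], loops_r$end1[j])
      b2 <- inside("chr1", tssi, loops_r$chrom2[j], loops_r$start2[j], loops_r$end2[j])
      if ((a1 && b2) || (a2 && b1)) want <- TRUE
    }
    expect_equal(got$loop_supported[i], want)
  }
})

test_that("gene-pair loop support uses gene-body overlap", {
  loops <- loop_set(data.frame(
    chrom1 = "chr1", start1 = 1000L, end1 = 2000L,
    chrom2 = "chr1", start2 = 9000L, end2 = 10000L))
  ann <- gene_annotation(data.frame(
    gene_id = c("A", "B", "C"), chrom = "chr1",
    start = c(1500L, 9500L, 5000L), end = c(2600L, 10500L, 6000L),
    strand = "+", biotype = c("lncRNA", "protein_coding", "protein_coding")))
  gp <- data.frame(gene1 = c("A", "A"), gene2 = c("B", "C"))
  res <- loop_support_genes(gp, loops, ann)
  expect_equal(res$loop_supported, c(TRUE, FALSE))
})
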