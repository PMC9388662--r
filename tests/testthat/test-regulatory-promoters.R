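mk_annot <- function(df) gene_annotation(df)

test_that("promoter windows follow the strand-aware convention", {
  ann <- mk_annot(data.frame(
    gene_id = c("p", "m"), chrom = "chr1",
    start = c(999L, 500L), end = c(2000L, 1000L),
    strand = c("+", "-"), biotype = "lncRNA"))
  # + strand gene: tss = start = 999
  pw <- promoter_windows(ann, upstream = 200, downstream = 100)
  expect_equal(pw$start[pw$lnc_id == "p"], 799L)
  expect_equal(pw$end[pw$lnc_id == "p"], 1099L)
  # - strand gene: tss = end - 1 = 999
  expect_equal(pw$start[pw$lnc_id == "m"], 900L)
  expect_equal(pw$end[pw$lnc_id == "m"], 1200L)
  expect_equal(unique(pw$end - pw$start), 300L)
  # both windows contain the TSS base
  expect_true(all(pw$start <= pw$tss & pw$tss < pw$end))

  # upstream = 0, downstream = 1: exactly the TSS base
  pw1 <- promoter_windows(ann, upstream = 0, downstream = 1)
  expect_equal(pw1$end - pw1$start, c(1L, 1L))
  expect_equal(pw1$start, pw1$tss)

  expect_error(promoter_windows(ann, 200, 100,
                                chrom_sizes = c(chr1 = 900)), "outside")
})

test_that("independence classification equals a brute-force padded scan", {
  lnc <- mk_annot(data.frame(
    gene_id = c("inside", "abut", "clear"), chrom = "chr1",
    start = c(5000L, 3800L, 9000L), end = c(5300L, 4100L, 9300L),
    strand = "+", biotype = "lncRNA"))
  pc <- mk_annot(data.frame(
    gene_id = "host", chrom = "chr1", start = 4300L, end = 6000L,
    strand = "+", biotype = "protein_coding"))
  prom <- promoter_windows(lnc, 200, 100)
  # promoter of "abut": [3600, 3900); padded host locus starts at 4100
  res <- classify_independent(prom, pc, pad_upstream = 200)
  flags <- stats::setNames(res$independent, res$lnc_id)
  expect_false(flags[["inside"]])
  expect_true(flags[["abut"]])   # half-open abutment is not overlap
  expect_true(flags[["clear"]])
  # 1 bp into the padded region flips the flag
  res2 <- classify_independent(prom, pc, pad_upstream = 401)
  expect_false(stats::setNames(res2$independent, res2$lnc_id)[["abut"]])
  expect_error(classify_independent(prom, pc, pad_upstream = -1), ">= 0")

  # no protein-coding genes and pad 0: everything independent
  res3 <- classify_independent(prom, lnc, pad_upstream = 0)
  expect_true(all(res3$independent))

  # random fixture vs exhaustive double loop
  set.seed(51)
  n <- 300
  s <- sample.int(5e5, n)
  lncr <- mk_annot(data.frame(
    gene_id = paste0("L", 1:n), chrom = sample(paste0("chr", 1:3), n, TRUE),
    start = s, end = s + sample(300:2000, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE), biotype = "lncRNA"))
  s2 <- sample.int(5e5, n)
  pcr <- mk_annot(data.frame(
    gene_id = paste0("P", 1:n), chrom = sample(paste0("chr", 1:3), n, TRUE),
    start = s2, end = s2 + sample(500:5000, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE), biotype = "protein_coding"))
  promr <- promoter_windows(lncr, 200, 100)
  got <- classify_independent(promr, pcr, pad_upstream = 200)$independent
  pad_s <- ifelse(pcr$strand == "+", pcr$start - 200L, pcr$start)
  pad_e <- ifelse(pcr$strand == "+", pcr$end, pcr$end + 200L)
  want <- !bf_any_hit(promr, data.frame(chrom = pcr$chrom,
                                        start = pmax(pad_s, 0), end = pad_e))
  expect_equal(got, want)
})

test_that("nearest gene assignment matches brute force with tie-breaks", {
  pc <- mk_annot(data.frame(
    gene_id = c("left", "right"), chrom = "chr1",
    start = c(1000L, 3000L), end = c(1500L, 3500L),
    strand = "+", biotype = "protein_coding"))
  lnc <- mk_annot(data.frame(
    gene_id = "mid", chrom = "chr1", start = 2100L, end = 2500L,
    strand = "+", biotype = "lncRNA"))
  prom <- promoter_windows(lnc, 200, 100)  # [1900, 2200)
  res <- nearest_pc_gene(prom, pc)
  expect_equal(res$nearest_pc_gene, "left")  # 400 vs 800; left wins
  expect_equal(res$distance, -400)            # upstream -> negative

  # exact equidistance: smaller start coordinate wins
  pc_eq <- mk_annot(data.frame(
    gene_id = c("b", "a"), chrom = "chr1",
    start = c(2600L, 1000L), end = c(3100L, 1500L),
    strand = "+", biotype = "protein_coding"))
  res_eq <- nearest_pc_gene(prom, pc_eq)
  expect_equal(res_eq$nearest_pc_gene, "a")

  # random fixture vs brute force
  set.seed(52)
  n <- 150
  s <- sample.int(2e5, n)
  lncr <- mk_annot(data.frame(
    gene_id = paste0("L", 1:n), chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = s, end = s + 500L, strand = "+", biotype = "lncRNA"))
  s2 <- sample.int(2e5, 80)
  pcr <- mk_annot(data.frame(
    gene_id = paste0("P", 1:80), chrom = sample(c("chr1", "chr2"), 80, TRUE),
    start = s2, end = s2 + 1000L, strand = "+", biotype = "protein_coding"))
  promr <- promoter_windows(lncr, 200, 100)
  got <- nearest_pc_gene(promr, pcr)
  for (i in seq_len(nrow(promr))) {
    cand <- pcr[pcr$chrom == promr$chrom[i], ]
    gap <- pmax(cand$start - promr$end[i], promr$start[i] - cand$end, 0)
    best <- which(gap == min(gap))
    if (length(best) > 1) best <- best[which.min(cand$start[best])]
    expect_equal(got$nearest_pc_gene[i], cand$gene_id[best])
    expect_equal(abs(got$distance[i]), min(gap))
  }
})

test_that("ATAC promoter contrast averages containing peaks per sample", {
  peaks <- genomic_intervals(c("chr1", "chr1"), c(100L, 5000L),
                             c(700L, 5600L), c("pk1", "pk2"))
  sig <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = list(c("pk1", "pk2"), c("s1", "s2")))
  atac <- atac_matrix(sig, peaks)
  prom <- structure(data.frame(lnc_id = "l1", chrom = "chr1", start = 300L,
                               end = 600L, strand = "+", tss = 500L),
                    class = c("PromoterSet", "data.frame"))
  clin <- clinical_table(data.frame(sample_id = c("s1", "s2"),
                                    er_status = c("pos", "neg"),
                                    her2_status = NA, pam50 = NA,
                                    os_time = NA, os_event = NA))
  res <- atac_promoter_contrast(atac, prom, clin)
  expect_equal(res$sample_means, sig["pk1", ])  # only pk1 contains it
  expect_equal(res$n_peaks, 1L)
  prom_off <- prom; prom_off$start <- 90000L; prom_off$end <- 90300L
  expect_error(atac_promoter_contrast(atac, prom_off, clin), "no peak")
})

test_that("chromHMM promoter enrichment ranks planted states on top", {
  set.seed(53)
  n <- 60
  s <- seq(0, by = 10000L, length.out = n)
  ann <- mk_annot(data.frame(
    gene_id = paste0("L", 1:n), chrom = "chr1", start = s + 2000L,
    end = s + 3000L, strand = "+", biotype = "lncRNA"))
  prom <- promoter_windows(ann, 200, 100)
  # EhAct segments placed exactly over the first 20 promoters, QsLow elsewhere
  segs <- rbind(
    genomic_intervals("chr1", prom$start[1:20], prom$end[1:20], "EhAct"),
    genomic_intervals("chr1", prom$start[21:60], prom$end[21:60], "QsLow"))
  track <- segmentation_track("mcf7_like", segs)
  res <- chromhmm_promoter_enrichment(prom[1:20, ], track, prom,
                                      min_support = 10)
  expect_equal(res$term_id[1], "EhAct")
  expect_equal(res$overlap_count[res$term_id == "EhAct"], 20L)
  expect_lt(res$p[res$term_id == "EhAct"], 1e-6)

  # query == background: every ratio 1 and p 1
  res_all <- chromhmm_promoter_enrichment(prom, track, prom, min_support = 1)
  expect_true(all(res_all$ratio == 1))
  expect_true(all(res_all$p == 1))

  # a state supported by fewer than min_support query promoters is excluded
  segs9 <- rbind(genomic_intervals("chr1", prom$start[1:9], prom$end[1:9],
                                   "PrBiv"), segs)
  track9 <- segmentation_track("x", rbind(
    genomic_intervals("chr1", prom$start[1:9], prom$end[1:9], "PrBiv"),
    genomic_intervals("chr1", prom$start[10:60], prom$end[10:60], "QsLow")))
  res9 <- chromhmm_promoter_enrichment(prom[1:20, ], track9, prom,
                                       min_support = 10)
  expect_false("PrBiv" %in% res9$term_id)
})

test_that("TFBS enrichment builds the Fisher table per set", {
  set.seed(54)
  n <- 40
  s <- seq(0, by = 10000L, length.out = n)
  ann <- mk_annot(data.frame(
    gene_id = paste0("L", 1:n), chrom = "chr1", start = s + 2000L,
    end = s + 3000L, strand = "+", biotype = "lncRNA"))
  prom <- promoter_windows(ann, 200, 100)
  subset <- prom[1:10, ]
  hit_subset <- genomic_intervals("chr1", subset$tss - 10L, subset$tss + 10L,
                                  "site")
  hit_all <- genomic_intervals("chr1", prom$tss - 10L, prom$tss + 10L, "site")
  tf <- tfbs_collection(list(only_subset = hit_subset, everywhere = hit_all))
  res <- tfbs_promoter_enrichment(subset, tf, prom)
  # hitting every promoter cannot be enriched
  expect_equal(res$p[res$set_id == "everywhere"], 1)
  # hitting exactly the subset gives the minimal p for those margins
  expect_equal(res$p[res$set_id == "only_subset"],
               oracle_fisher_greater(10, 0, 0, 30), tolerance = 1e-12)
  expect_equal(res$n_hit_query[res$set_id == "only_subset"], 10L)
})
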