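#!/usr/bin/env Rscript
# Stage 7 -- distal regulatory elements: preprocess the CpG beta matrices
# (missingness filter, kNN imputation, IQR filter), correlate every CpG with
# every lncRNA on the same chromosome in both cohorts, keep inverse
# correlations that replicate under Bonferroni control, characterize the
# kept CpGs by chromatin state and accessibility, and validate pairs whose
# CpG and target TSS sit in two feet of the same chromatin loop.

library(lncscape)

dat <- "results/data"
out <- "results/methylation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annot <- read_annotation(file.path(dat, "genes.tsv"), convention = "0based")
pos <- read.delim(file.path(dat, "cpg_positions.tsv"))

meth <- list(); lnc <- list()
for (i in 1:2) {
  beta <- read_matrix_tsv(file.path(dat, sprintf("cohort%d_beta.tsv", i)))
  m <- methylation_matrix(beta, pos)
  meth[[i]] <- preprocess_methylation(m, max_missing = 0.5, knn_k = 10,
                                      iqr_min = 0.1)
  cat(sprintf("cohort %d: %d CpGs in, %d after preprocessing\n", i,
              nrow(beta), nrow(meth[[i]]$beta)))
  expr <- read_expression(file.path("results/prep",
                                    sprintf("cohort%d_log2.tsv", i)), "log2p1")
  lnc[[i]] <- expr[intersect(rownames(expr),
                             annot$gene_id[annot$biotype == "lncRNA"]), ]
}

cis <- cis_correlation(meth[[1]], lnc[[1]], meth[[2]], lnc[[2]], annot,
                       alpha = 0.05, direction = "negative")
cat(sprintf("tested %d same-chromosome pairs (the Bonferroni m); kept %d inverse pairs\n",
            cis$n_tests, nrow(cis$pairs)))

loops <- read_bedpe_loops(file.path(dat, "loops.bedpe"))
cis$pairs <- loop_support(cis$pairs, pos, loops, annot)
cat(sprintf("%d of %d kept pairs are supported by a chromatin loop\n",
            sum(cis$pairs$loop_supported), nrow(cis$pairs)))
write.table(cis$pairs, file.path(out, "cis_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# chromatin-state context of the kept CpGs against the full manifest
track <- segmentation_track("lumA_line",
                            read_bed(file.path(dat, "segmentation_lumA_line.bed")))
ctx <- cpg_context_enrichment(unique(cis$pairs$cpg_id), pos, track, pos$cpg_id)
cat("top chromatin states of the kept CpGs:\n")
print(head(ctx[, c("term_id", "overlap_count", "ratio", "p_adj")], 3))
write.table(ctx, file.path(out, "cpg_state_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# ER-dependent accessibility at peaks containing the kept CpGs, grouped by
# the target lncRNA's ER association
cons <- read.delim("results/de/consensus_er.tsv")
peaks <- read_bed(file.path(dat, "atac_peaks.bed"))
atac <- atac_matrix(read_matrix_tsv(file.path(dat, "cohort1_atac.tsv")), peaks)
clin <- read_clinical(file.path(dat, "cohort1_clinical.tsv"))
for (grp in c("replicated_up_g1", "replicated_up_g2")) {
  targets <- cons$gene_id[cons$status == grp]
  cg <- unique(cis$pairs$cpg_id[cis$pairs$lnc_id %in% targets])
  if (length(cg) == 0) next
  ac <- cpg_atac_contrast(cg, pos, atac, clin)
  cat(sprintf("ATAC at CpGs of %s lncRNAs: %d peaks, Wilcoxon p = %.2e\n",
              ifelse(grp == "replicated_up_g1", "ER+", "ER-"), ac$n_peaks, ac$p))
}

# recovery against the planted enhancer pairs
truth <- jsonlite::read_json(file.path(dat, "truth.json"),
                             simplifyVector = TRUE)
planted <- truth$reg_pairs
key <- function(d) paste(d$cpg_id, d$lnc_id)
tp <- sum(key(cis$pairs) %in% key(planted))
cat(sprintf("precision %.3f, recall %.3f vs %d planted pairs; loop flags match planted looped subset: %s\n",
            tp / nrow(cis$pairs), tp / nrow(planted), nrow(planted),
            setequal(key(cis$pairs)[cis$pairs$loop_supported],
                     key(planted)[planted$looped])))
jsonlite::write_json(list(n_tests = cis$n_tests, n_kept = nrow(cis$pairs),
                          precision = tp / nrow(cis$pairs),
                          recall = tp / nrow(planted),
                          n_loop_supported = sum(cis$pairs$loop_supported)),
                     file.path(out, "summary.json"), auto_unbox = TRUE)
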