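#!/usr/bin/env Rscript
# Stage 6 -- promoter characterization: -200/+100 strand-aware windows
# around every lncRNA TSS, classification against padded protein-coding
# loci, nearest-gene assignment for independent promoters, ER-dependent ATAC
# accessibility at promoter-containing peaks, and chromHMM / TFBS
# enrichment of the ER+-associated promoters.

library(lncscape)

dat <- "results/data"
out <- "results/promoters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annot <- read_annotation(file.path(dat, "genes.tsv"), convention = "0based")
prom <- promoter_windows(annot, upstream = 200, downstream = 100)
prom <- classify_independent(prom, annot, pad_upstream = 200)
cat(sprintf("%d lncRNA promoters; %d independent, %d overlapping a protein-coding locus\n",
            nrow(prom), sum(prom$independent), sum(!prom$independent)))

truth <- jsonlite::read_json(file.path(dat, "truth.json"))
want <- unlist(truth$promoter_class)[prom$lnc_id] == "independent"
cat(sprintf("agreement with planted promoter classes: %.3f\n",
            mean(prom$independent == want)))

near <- nearest_pc_gene(prom[prom$independent, ], annot)
write.table(merge(as.data.frame(prom), near, by = "lnc_id"),
            file.path(out, "promoters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# ER+/ER- associated promoter subsets from the replicated DE calls
cons <- read.delim("results/de/consensus_er.tsv")
er_pos <- cons$gene_id[cons$status == "replicated_up_g1"]
er_neg <- cons$gene_id[cons$status == "replicated_up_g2"]
prom_pos <- prom[prom$lnc_id %in% er_pos, ]
prom_neg <- prom[prom$lnc_id %in% er_neg, ]

peaks <- read_bed(file.path(dat, "atac_peaks.bed"))
sig <- read_matrix_tsv(file.path(dat, "cohort1_atac.tsv"))
atac <- atac_matrix(sig, peaks)
clin <- read_clinical(file.path(dat, "cohort1_clinical.tsv"))
for (nm in c("pos", "neg")) {
  sub <- if (nm == "pos") prom_pos else prom_neg
  if (nrow(sub) == 0) next
  ac <- atac_promoter_contrast(atac, sub, clin)
  cat(sprintf("ATAC at ER%s-associated promoters: %d peaks, ER+ vs ER- Wilcoxon p = %.2e\n",
              ifelse(nm == "pos", "+", "-"), ac$n_peaks, ac$p))
}

# chromHMM enrichment of ER+-associated promoters, per cell line
seg_files <- list.files(dat, pattern = "^segmentation_.*\\.bed$",
                        full.names = TRUE)
chrom_res <- do.call(rbind, lapply(seg_files, function(f) {
  cl <- sub("^segmentation_(.*)\\.bed$", "\\1", basename(f))
  track <- segmentation_track(cl, read_bed(f))
  chromhmm_promoter_enrichment(prom_pos, track, prom, min_support = 10)
}))
cat("top chromatin states at ER+-associated promoters:\n")
print(head(chrom_res[order(chrom_res$p), c("term_id", "cell_line", "ratio",
                                           "p_adj")], 4))
write.table(chrom_res, file.path(out, "chromhmm_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# TFBS-set enrichment (Fisher exact, one-sided)
tfbs_files <- list.files(file.path(dat, "tfbs"), full.names = TRUE)
tfbs <- tfbs_collection(stats::setNames(lapply(tfbs_files, read_bed),
                                        sub("\\.bed$", "",
                                            basename(tfbs_files))))
tf_res <- tfbs_promoter_enrichment(prom_pos, tfbs, prom)
cat("top TFBS sets at ER+-associated promoters:\n")
print(head(tf_res[, c("set_id", "n_hit_query", "odds_ratio", "p_adj")], 5))
write.table(tf_res, file.path(out, "tfbs_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
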