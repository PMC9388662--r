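#!/usr/bin/env Rscript
# Stage 1 -- simulate the study: a genome annotation with chromatin-state
# tracks, TFBS sets, ATAC peaks, CpGs and chromatin loops; two bulk cohorts
# of 300 samples sharing gene-level truth; survival outcomes; and a
# cell-type-labeled single-cell dataset. Everything downstream reads the
# plain-text files written here.

library(lncscape)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/data"
dir.create(file.path(out, "tfbs"), recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genome <- generate_genome(cfg)
audit_truth(genome)
cat(sprintf("genome: %d genes on %d chromosomes, %d CpGs, %d loops\n",
            nrow(genome$annotation), cfg$n_chrom,
            nrow(genome$cpg_positions), nrow(genome$loops)))

write_annotation(genome$annotation, file.path(out, "genes.tsv"))
for (seg in genome$segmentations)
  write_bed(seg$segments, file.path(out, paste0("segmentation_",
                                                seg$cell_line, ".bed")))
write_bed(genome$atac_peaks, file.path(out, "atac_peaks.bed"))
write.table(genome$cpg_positions, file.path(out, "cpg_positions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bedpe_loops(genome$loops, file.path(out, "loops.bedpe"))
for (nm in names(genome$tfbs))
  write_bed(genome$tfbs[[nm]], file.path(out, "tfbs", paste0(nm, ".bed")))

for (i in 1:2) {
  co <- generate_survival(generate_cohort(genome, i), genome)
  cat(sprintf("cohort %d: %d samples, %.0f%% ER+, event rate %.2f\n", i,
              nrow(co$clinical), 100 * mean(co$clinical$er_status == "pos"),
              mean(co$clinical$os_event)))
  write_expression(co$expr, file.path(out, sprintf("cohort%d_expr_tpm.tsv", i)))
  write_clinical(co$clinical, file.path(out, sprintf("cohort%d_clinical.tsv", i)))
  write_matrix_tsv(co$meth$beta,
                              file.path(out, sprintf("cohort%d_beta.tsv", i)),
                              "cpg_id")
  write_matrix_tsv(co$atac$signal,
                              file.path(out, sprintf("cohort%d_atac.tsv", i)),
                              "peak_id")
}

sc <- generate_single_cell(genome)
write_single_cell(sc, file.path(out, "single_cell"))
cat(sprintf("single cell: %d genes x %d cells over %d types\n",
            nrow(sc$counts), ncol(sc$counts), length(unique(sc$cell_type))))

truth <- genome$truth
jsonlite::write_json(
  list(seed = seed,
       lnc_cluster = as.list(truth$lnc_cluster),
       mrna_cluster = as.list(truth$mrna_cluster),
       driver = as.list(truth$driver),
       de_truth = as.list(truth$de_truth),
       prognostic = as.list(truth$prognostic),
       reg_pairs = truth$reg_pairs,
       promoter_class = as.list(truth$promoter_class),
       tfbs_bias = as.list(truth$tfbs_bias),
       esr1_gene = truth$esr1_gene),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
cat("wrote inputs and truth.json under", out, "\n")
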