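#!/usr/bin/env Rscript
# Stage 5 -- cell-type attribution: model each lncRNA's expression as a
# function of ESR1 expression, a fibroblast signature score and a lymphocyte
# signature score (all standardized), assign each lncRNA to its strongest
# explanatory variable, compare coefficients across the three co-expression
# clusters, and verify the attribution in the single-cell compartment.

library(lncscape)

dat <- "results/data"
out <- "results/attribution"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annot <- read_annotation(file.path(dat, "genes.tsv"), convention = "0based")
expr <- read_expression("results/prep/cohort1_log2.tsv", "log2p1")
lnc <- expr[intersect(rownames(expr),
                      annot$gene_id[annot$biotype == "lncRNA"]), ]
mrna <- expr[intersect(rownames(expr),
                       annot$gene_id[annot$biotype == "protein_coding"]), ]

truth <- jsonlite::read_json(file.path(dat, "truth.json"))
mrna_cluster <- unlist(truth$mrna_cluster)
esr1_gene <- truth$esr1_gene
fib_set <- names(mrna_cluster)[mrna_cluster == "B"]
lym_set <- names(mrna_cluster)[mrna_cluster == "C"]

esr1 <- unclass(mrna)[esr1_gene, ]
fib <- signature_score(mrna, fib_set)
lym <- signature_score(mrna, lym_set)
cat(sprintf("signature coverage: fibroblast %.0f%%, lymphocyte %.0f%%\n",
            100 * fib$coverage, 100 * lym$coverage))

att <- glm_attribution(lnc, esr1, fib$score, lym$score)
write.table(att, file.path(out, "attribution.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

clusters <- read.delim("results/coexpression/clusters.tsv")
lnc_labels <- with(clusters[clusters$gene_id %in% rownames(lnc), ],
                   stats::setNames(cluster, gene_id))
cmp <- compare_cluster_coefficients(att, lnc_labels)
cat("Kruskal-Wallis separation of coefficients across clusters:\n")
print(cmp$kw)
cat("best-variable fractions per cluster:\n")
print(cmp$fractions)
write.table(cmp$fractions, file.path(out, "cluster_fractions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# single-cell verification: dot-plot summary of clustered lncRNAs
sc <- read_single_cell(file.path(dat, "single_cell"))
norm <- sc_lognormalize(sc, scale_factor = 10000)
lnc_truth <- unlist(truth$lnc_cluster)
show <- unlist(lapply(c("1", "2", "3"), function(k)
  head(names(lnc_truth)[lnc_truth == k &
                          names(lnc_truth) %in% rownames(sc$counts)], 10)))
dots <- dotplot_summary(sc, norm, show)
write.table(dots, file.path(out, "sc_dotplot.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
home <- c(`1` = "cancer_epithelial", `2` = "CAF", `3` = "T")
for (k in names(home)) {
  genes <- show[lnc_truth[show] == k]
  sub <- dots[dots$gene_id %in% genes, ]
  top <- sub$cell_type[order(-sub$mean_norm_expr)][1]
  cat(sprintf("cluster %s lncRNAs: highest mean expression in %s\n", k, top))
}

mark <- marker_test_one_vs_rest(norm$norm[show, ], norm$cell_type)
write.table(mark, file.path(out, "sc_markers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote attribution tables under", out, "\n")
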