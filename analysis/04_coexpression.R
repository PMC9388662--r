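#!/usr/bin/env Rscript
# Stage 4 -- the co-expression engine: Spearman correlation of every lncRNA
# against every mRNA in both cohorts, Bonferroni-replicated edges, the
# above-average-degree and |rho| > 0.4 filters, binarization to -1/+1 and
# 3 x 3 hierarchical biclustering, annotated with the ER consensus calls.

library(lncscape)

dat <- "results/data"
out <- "results/coexpression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annot <- read_annotation(file.path(dat, "genes.tsv"), convention = "0based")
sets <- lapply(1:2, function(i) {
  expr <- read_expression(file.path("results/prep",
                                    sprintf("cohort%d_log2.tsv", i)), "log2p1")
  list(lnc = expr[intersect(rownames(expr),
                            annot$gene_id[annot$biotype == "lncRNA"]), ],
       mrna = expr[intersect(rownames(expr),
                             annot$gene_id[annot$biotype == "protein_coding"]), ])
})

corA <- spearman_pair_matrix(sets[[1]]$lnc, sets[[1]]$mrna)
corB <- spearman_pair_matrix(sets[[2]]$lnc, sets[[2]]$mrna)
edges <- bonferroni_replicated_edges(corA, corB, alpha = 0.05)
cat(sprintf("tested %d pairs per cohort; %d replicated edges (%d sign conflicts)\n",
            edges$n_tests_A, nrow(edges$edges), edges$n_sign_conflict))

filtered <- degree_and_rho_filter(edges, rho_min = 0.4)
cat(sprintf("mean degrees %.1f (lncRNA) / %.1f (mRNA); %d lncRNAs and %d mRNAs above average; %d edges pass |rho| > 0.4\n",
            filtered$mean_lnc_degree, filtered$mean_mrna_degree,
            length(filtered$lnc_retained), length(filtered$mrna_retained),
            nrow(filtered$edges)))
write.table(filtered$edges, file.path(out, "edges_filtered.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

bic <- binarize_bicluster(filtered, k_rows = 3, k_cols = 3)
pos_frac <- mean(bic$matrix[bic$matrix != 0] == 1)
cat(sprintf("binarized matrix %d x %d; %.1f%% of entries positive\n",
            nrow(bic$matrix), ncol(bic$matrix), 100 * pos_frac))
write.table(data.frame(gene_id = c(names(bic$lnc_labels), names(bic$mrna_labels)),
                       cluster = c(as.character(bic$lnc_labels),
                                   bic$mrna_labels)),
            file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# annotate lncRNA clusters with the replicated ER calls
cons_tab <- read.delim("results/de/consensus_er.tsv")
ann <- annotate_clusters(bic$lnc_labels, list(er = list(table = cons_tab)))
print(ann)
write.table(ann, file.path(out, "cluster_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# score the partition against the planted truth
truth <- jsonlite::read_json(file.path(dat, "truth.json"))
lnc_truth <- unlist(truth$lnc_cluster)
ari <- adjusted_rand_index(bic$lnc_labels, lnc_truth[names(bic$lnc_labels)])
cat(sprintf("adjusted Rand index vs planted lncRNA clusters: %.3f\n", ari))
jsonlite::write_json(list(n_tests = edges$n_tests_A,
                          n_replicated_edges = nrow(edges$edges),
                          n_filtered_edges = nrow(filtered$edges),
                          positive_fraction = pos_frac,
                          ari_lnc = ari),
                     file.path(out, "summary.json"), auto_unbox = TRUE)
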