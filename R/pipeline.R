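# End-to-end orchestration over a synthetic run: simulate -> prep -> DE /
# survival -> co-expression biclustering -> cell-type attribution ->
# promoter characterization -> cis methylation; every stage's outputs and
# counts land in a manifest, and self_check() scores recovery against the
# planted truth.

split_by_biotype <- function(expr, annot) {
  lnc <- annot$gene_id[annot$biotype == "lncRNA"]
  mrna <- annot$gene_id[annot$biotype == "protein_coding"]
  list(lnc = expr[intersect(rownames(expr), lnc), , drop = FALSE],
       mrna = expr[intersect(rownames(expr), mrna), , drop = FALSE])
}

#' Run the full synthetic analysis pipeline
#'
#' Generates the genome and both cohorts from `cfg`, then executes every
#' analysis stage in dependency order and (optionally) writes all standard-
#' format outputs plus `truth.json` and a JSON run manifest under `out_dir`.
#'
#' @param cfg [sim_config()].
#' @param out_dir optional output directory; NULL skips file output.
#' @param run_methylation,run_single_cell toggle the optional stages.
#' @return list with all stage results (`genome`, `cohorts`, `prep`, `de`,
#'   `survival`, `coexpression`, `attribution`, `promoters`, `methylation`,
#'   `single_cell`) and `manifest`.
#' @export
run_all <- function(cfg = sim_config(), out_dir = NULL,
                    run_methylation = TRUE, run_single_cell = TRUE) {
  manifest <- list(seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "seed")],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # ---- simulate
  genome <- generate_genome(cfg)
  audit_truth(genome)
  cohorts <- list(generate_cohort(genome, 1), generate_cohort(genome, 2))
  cohorts <- lapply(cohorts, generate_survival, genome = genome)
  note("simulate", n_genes = nrow(genome$annotation),
       n_cpgs = nrow(genome$cpg_positions), n_loops = nrow(genome$loops),
       n_samples = vapply(cohorts, function(co) ncol(co$expr), 0L))

  # ---- prep (filters + transform), per cohort
  prep <- lapply(cohorts, function(co) prep_expression(co$expr))
  note("prep",
       funnel = lapply(prep, function(p) p$report[c("n_input_genes", "n_pass_tpm", "n_pass_iqr")]),
       thresholds = list(min_tpm = 1, min_fraction = 0.05, iqr = 0.1))
  annot <- genome$annotation
  sets <- lapply(prep, function(p) split_by_biotype(p$expr, annot))

  # ---- differential expression (ER contrast) + consensus
  de <- lapply(seq_along(cohorts), function(i)
    moderated_t_de(sets[[i]]$lnc, cohorts[[i]]$clinical$er_status, group1 = "pos"))
  consensus <- cross_cohort_consensus(de[[1]]$table, de[[2]]$table)
  note("de", n_replicated = consensus$n_replicated,
       n_discordant = consensus$n_discordant,
       concordance_r = consensus$concordance_r, alpha = 0.05)

  # ---- survival screen (cohort 1, ER strata)
  surv <- cox_screen(sets[[1]]$lnc, cohorts[[1]]$clinical,
                     strata = cohorts[[1]]$clinical$er_status)
  note("survival", n_tested = nrow(surv),
       n_sig = sum(surv$p_adj < 0.05, na.rm = TRUE))

  # ---- co-expression biclustering
  corA <- spearman_pair_matrix(sets[[1]]$lnc, sets[[1]]$mrna)
  corB <- spearman_pair_matrix(sets[[2]]$lnc, sets[[2]]$mrna)
  edges <- bonferroni_replicated_edges(corA, corB, alpha = 0.05)
  filtered <- degree_and_rho_filter(edges, rho_min = 0.4)
  bic <- binarize_bicluster(filtered, k_rows = 3, k_cols = 3)
  annotation <- annotate_clusters(bic$lnc_labels, list(er = consensus))
  note("coexpress", n_pairs_tested = edges$n_tests_A,
       n_replicated_edges = nrow(edges$edges),
       n_sign_conflict = edges$n_sign_conflict,
       n_edges_after_filter = nrow(filtered$edges),
       n_lnc_clustered = length(bic$lnc_labels),
       n_mrna_clustered = length(bic$mrna_labels),
       alpha = 0.05, rho_min = 0.4, k = 3)

  # ---- cell-type attribution (cohort 1)
  truth <- genome$truth
  esr1 <- unclass(sets[[1]]$mrna)[truth$esr1_gene, ]
  fib_sig <- names(truth$mrna_cluster)[truth$mrna_cluster == "B"]
  lym_sig <- names(truth$mrna_cluster)[truth$mrna_cluster == "C"]
  fib_score <- signature_score(sets[[1]]$mrna, fib_sig)$score
  lym_score <- signature_score(sets[[1]]$mrna, lym_sig)$score
  attribution <- glm_attribution(sets[[1]]$lnc, esr1, fib_score, lym_score)
  cluster_attr <- tryCatch(
    compare_cluster_coefficients(attribution, bic$lnc_labels),
    error = function(e) {
      warning("cluster coefficient comparison skipped: ", conditionMessage(e))
      NULL
    })
  note("attribute",
       kw_p = if (is.null(cluster_attr)) NA_real_ else cluster_attr$kw$p,
       fractions = if (is.null(cluster_attr)) NULL else cluster_attr$fractions)

  # ---- single cell
  sc_res <- NULL
  if (run_single_cell) {
    sc <- generate_single_cell(genome)
    norm <- sc_lognormalize(sc)
    show_genes <- names(truth$lnc_cluster)[truth$lnc_cluster != "none"]
    show_genes <- utils::head(show_genes, 30)
    dots <- if (length(show_genes)) dotplot_summary(sc, norm, show_genes) else NULL
    sc_res <- list(dataset = sc, dotplot = dots)
    note("single_cell", n_cells = ncol(sc$counts))
  }

  # ---- promoters
  prom <- promoter_windows(annot, upstream = 200, downstream = 100)
  prom <- classify_independent(prom, annot, pad_upstream = 200)
  nearest <- nearest_pc_gene(prom[prom$independent, , drop = FALSE], annot)
  er_pos_lnc <- consensus$table$gene_id[consensus$table$status == "replicated_up_g1"]
  er_neg_lnc <- consensus$table$gene_id[consensus$table$status == "replicated_up_g2"]
  prom_pos <- prom[prom$lnc_id %in% er_pos_lnc, , drop = FALSE]
  prom_neg <- prom[prom$lnc_id %in% er_neg_lnc, , drop = FALSE]
  atac_pos <- if (nrow(prom_pos)) atac_promoter_contrast(cohorts[[1]]$atac, prom_pos,
                                                         cohorts[[1]]$clinical) else NULL
  atac_neg <- if (nrow(prom_neg)) atac_promoter_contrast(cohorts[[1]]$atac, prom_neg,
                                                         cohorts[[1]]$clinical) else NULL
  chromhmm <- if (nrow(prom_pos)) lapply(genome$segmentations, function(seg)
    chromhmm_promoter_enrichment(prom_pos, seg, prom, min_support = 10)) else NULL
  tfbs_enr <- if (nrow(prom_pos)) tfbs_promoter_enrichment(prom_pos, genome$tfbs, prom) else NULL
  note("promoters", n_promoters = nrow(prom),
       n_independent = sum(prom$independent),
       n_er_pos = nrow(prom_pos), n_er_neg = nrow(prom_neg),
       window = c(200, 100), pad = 200, min_support = 10)

  # ---- cis methylation
  meth_res <- NULL
  if (run_methylation) {
    methA <- preprocess_methylation(cohorts[[1]]$meth)
    methB <- preprocess_methylation(cohorts[[2]]$meth)
    cis <- cis_correlation(methA, sets[[1]]$lnc, methB, sets[[2]]$lnc, annot,
                           alpha = 0.05, direction = "negative")
    cis$pairs <- loop_support(cis$pairs, genome$cpg_positions, genome$loops, annot)
    ctx <- if (nrow(cis$pairs)) cpg_context_enrichment(
      unique(cis$pairs$cpg_id), genome$cpg_positions, genome$segmentations[[1]],
      genome$cpg_positions$cpg_id) else NULL
    meth_res <- list(methA = methA, methB = methB, cis = cis, context = ctx)
    note("methcis", n_cpg_after_prep = c(nrow(methA$beta), nrow(methB$beta)),
         bonferroni_m = cis$n_tests, n_kept_pairs = nrow(cis$pairs),
         n_loop_supported = sum(cis$pairs$loop_supported),
         max_missing = 0.5, knn_k = 10, iqr_min = 0.1)
  }

  result <- list(genome = genome, cohorts = cohorts, prep = prep, de = de,
                 consensus = consensus, survival = surv,
                 coexpression = list(edges = edges, filtered = filtered,
                                     bicluster = bic, annotation = annotation),
                 attribution = list(table = attribution, clusters = cluster_attr),
                 promoters = list(set = prom, nearest = nearest,
                                  atac_pos = atac_pos, atac_neg = atac_neg,
                                  chromhmm = chromhmm, tfbs = tfbs_enr),
                 methylation = meth_res, single_cell = sc_res,
                 manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

# serialize the standard-format outputs of a run
write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  genome <- res$genome
  write_annotation(genome$annotation, p("genes.tsv"))
  for (seg in genome$segmentations)
    write_bed(seg$segments, p(paste0("segmentation_", seg$cell_line, ".bed")))
  write_bed(genome$atac_peaks, p("atac_peaks.bed"))
  utils::write.table(genome$cpg_positions, p("cpg_positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bedpe_loops(genome$loops, p("loops.bedpe"))
  for (i in seq_along(res$cohorts)) {
    co <- res$cohorts[[i]]
    write_expression(co$expr, p(sprintf("cohort%d_expr_tpm.tsv", i)))
    write_clinical(co$clinical, p(sprintf("cohort%d_clinical.tsv", i)))
    write_matrix_tsv(co$meth$beta, p(sprintf("cohort%d_beta.tsv", i)), "cpg_id")
    write_matrix_tsv(co$atac$signal, p(sprintf("cohort%d_atac.tsv", i)), "peak_id")
  }
  utils::write.table(res$consensus$table, p("de_consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$survival, p("survival_screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$coexpression$edges$edges, p("edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bic <- res$coexpression$bicluster
  utils::write.table(
    data.frame(gene_id = c(names(bic$lnc_labels), names(bic$mrna_labels)),
               cluster = c(as.character(bic$lnc_labels), bic$mrna_labels)),
    p("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$attribution$table, p("attribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$promoters$set), p("promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$methylation))
    utils::write.table(res$methylation$cis$pairs, p("cis_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$single_cell)) {
    write_single_cell(res$single_cell$dataset, p("single_cell"))
    if (!is.null(res$single_cell$dotplot))
      utils::write.table(res$single_cell$dotplot, p("sc_dotplot.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  truth <- res$genome$truth
  jsonlite::write_json(
    list(lnc_cluster = as.list(truth$lnc_cluster),
         mrna_cluster = as.list(truth$mrna_cluster),
         driver = as.list(truth$driver),
         de_truth = as.list(truth$de_truth),
         prognostic = as.list(truth$prognostic),
         reg_pairs = truth$reg_pairs,
         promoter_class = as.list(truth$promoter_class),
         tfbs_bias = as.list(truth$tfbs_bias)),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Score a synthetic run against its planted truth
#'
#' Computes the recovery metrics of a [run_all()] result: adjusted Rand
#' index of the lncRNA (and mRNA) biclusters vs truth, per-cluster
#' best-variable attribution fractions, precision/recall of the kept cis
#' pairs vs the planted enhancer pairs, exactness of the loop-supported set,
#' sign precision of the replicated DE calls, and mean recovered log-hazard
#' of the prognostic genes.
#'
#' @param res result of [run_all()].
#' @return named list of metrics.
#' @export
self_check <- function(res) {
  truth <- res$genome$truth
  bic <- res$coexpression$bicluster
  ari_lnc <- adjusted_rand_index(bic$lnc_labels,
                                 truth$lnc_cluster[names(bic$lnc_labels)])
  ari_mrna <- adjusted_rand_index(bic$mrna_labels,
                                  truth$mrna_cluster[names(bic$mrna_labels)])

  # attribution: map each truth cluster to its planted driver
  att <- res$attribution$table
  driver_of <- c(`1` = "ESR1", `2` = "fibroblast", `3` = "lymphocyte")
  att_frac <- vapply(names(driver_of), function(k) {
    members <- names(truth$lnc_cluster)[truth$lnc_cluster == k]
    got <- att$best_variable[match(members, att$lnc_id)]
    mean(got == driver_of[[k]], na.rm = TRUE)
  }, numeric(1))

  # DE sign precision of replicated calls vs planted lfc signs
  cons <- res$consensus$table
  called <- cons[startsWith(cons$status, "replicated"), , drop = FALSE]
  tr <- truth$de_truth[called$gene_id]
  de_precision <- if (nrow(called)) mean(sign(tr) == sign(called$logFC_A) & tr != 0)
  else NA_real_

  # cis pairs vs planted enhancer pairs
  metrics_cis <- c(precision = NA_real_, recall = NA_real_, loop_exact = NA_real_)
  if (!is.null(res$methylation)) {
    kept <- res$methylation$cis$pairs
    planted <- truth$reg_pairs
    key <- function(d) paste(d$cpg_id, d$lnc_id)
    tp <- sum(key(kept) %in% key(planted))
    metrics_cis["precision"] <- if (nrow(kept)) tp / nrow(kept) else NA_real_
    metrics_cis["recall"] <- if (nrow(planted)) tp / nrow(planted) else NA_real_
    looped_truth <- key(planted)[planted$looped]
    flagged <- key(kept)[kept$loop_supported]
    metrics_cis["loop_exact"] <-
      as.numeric(setequal(flagged, intersect(looped_truth, key(kept))))
  }

  # prognostic recovery: mean Cox beta at the planted genes (ER+ stratum)
  prog_genes <- names(truth$prognostic)[truth$prognostic != 0]
  sv <- res$survival
  sv_pos <- sv[sv$stratum == "pos" & sv$gene_id %in% prog_genes, , drop = FALSE]
  beta_hat <- if (nrow(sv_pos)) mean(sv_pos$beta, na.rm = TRUE) else NA_real_

  list(ari_lnc = ari_lnc, ari_mrna = ari_mrna,
       attribution_frac = att_frac, de_sign_precision = de_precision,
       cis_precision = unname(metrics_cis["precision"]),
       cis_recall = unname(metrics_cis["recall"]),
       loop_exact = unname(metrics_cis["loop_exact"]),
       prognostic_beta_mean = beta_hat,
       kw_p = if (is.null(res$attribution$clusters)) NA_real_ else
         res$attribution$clusters$kw$p)
}
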