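# Cis methylation-expression discovery: CpG preprocessing (missingness
# filter, kNN imputation, IQR filter), same-chromosome Spearman correlation
# replicated across two cohorts with Bonferroni control, chromatin-state and
# accessibility context of the kept CpGs, and loop-anchor validation.

#' Preprocess a methylation beta matrix
#'
#' Drops CpGs whose missing fraction exceeds `max_missing`, imputes each
#' remaining missing entry with the mean beta of the CpG's `knn_k` nearest
#' neighbors (Euclidean distance between CpG profiles with missing entries
#' held at the CpG's own mean, the standard k-nearest-neighbour array
#' imputation; distance ties broken by CpG id order), then retains CpGs with
#' IQR strictly above `iqr_min`.
#'
#' @param meth MethylationMatrix.
#' @param max_missing maximum tolerated missing fraction per CpG.
#' @param knn_k number of neighbor CpGs for imputation.
#' @param iqr_min IQR threshold after imputation.
#' @return MethylationMatrix with no missing values.
#' @export
preprocess_methylation <- function(meth, max_missing = 0.5, knn_k = 10,
                                   iqr_min = 0.1) {
  beta <- meth$beta
  keep <- rowMeans(is.na(beta)) <= max_missing
  beta <- beta[keep, , drop = FALSE]
  if (nrow(beta) <= knn_k)
    stop("fewer than knn_k + 1 = ", knn_k + 1, " CpGs available for imputation")
  incomplete <- which(rowSums(is.na(beta)) > 0)
  if (length(incomplete)) {
    filled <- beta
    rmn <- rowMeans(beta, na.rm = TRUE)
    nas <- which(is.na(filled), arr.ind = TRUE)
    filled[nas] <- rmn[nas[, 1]]
    sq <- rowSums(filled^2)
    id_rank <- rank(rownames(beta), ties.method = "first")
    # chunked distance computation keeps memory bounded on large arrays
    chunk <- 500L
    for (lo in seq(1L, length(incomplete), by = chunk)) {
      rows <- incomplete[lo:min(lo + chunk - 1L, length(incomplete))]
      G <- filled[rows, , drop = FALSE] %*% t(filled)
      for (j in seq_along(rows)) {
        i <- rows[j]
        d2 <- sq[i] + sq - 2 * G[j, ]
        d2[i] <- Inf
        nb <- order(d2, id_rank)[seq_len(knn_k)]
        miss <- which(is.na(beta[i, ]))
        beta[i, miss] <- colMeans(filled[nb, miss, drop = FALSE])
      }
    }
  }
  iqr <- apply(beta, 1L, stats::IQR, type = 7)
  beta <- beta[iqr > iqr_min, , drop = FALSE]
  methylation_matrix(beta, meth$positions)
}

#' Replicated cis CpG-lncRNA Spearman correlation
#'
#' Tests only same-chromosome (CpG, lncRNA) pairs. Per cohort, Spearman rho
#' and the t-approximation p-value; the Bonferroni family size is the number
#' of same-chromosome pairs actually tested. A pair is kept iff significant
#' (p * m < alpha) in BOTH cohorts with matching sign; `direction` then
#' retains the negative (default), positive, or both-sign pairs.
#'
#' @param methA,methB preprocessed MethylationMatrix per cohort (shared CpGs).
#' @param lncA,lncB ExpressionMatrix (log2p1) per cohort (shared lncRNAs;
#'   samples matching the respective methylation matrix).
#' @param annot GeneAnnotation giving lncRNA chromosome and TSS.
#' @param alpha family-wise threshold.
#' @param direction "negative", "positive" or "both".
#' @return list with `pairs` (data.frame: cpg_id, lnc_id, chrom, rho_A, p_A,
#'   rho_B, p_B, distance_bp), `n_tests` (the Bonferroni m), `n_kept_any_sign`.
#' @export
cis_correlation <- function(methA, lncA, methB, lncB, annot, alpha = 0.05,
                            direction = c("negative", "positive", "both")) {
  direction <- match.arg(direction)
  cpgs <- intersect(rownames(methA$beta), rownames(methB$beta))
  lncs <- intersect(rownames(lncA), rownames(lncB))
  lncs <- intersect(lncs, annot$gene_id)
  pos <- methA$positions[match(cpgs, methA$positions$cpg_id), ]
  ann <- annot[match(lncs, annot$gene_id), ]
  chroms <- intersect(unique(pos$chrom), unique(ann$chrom))
  if (length(chroms) == 0) stop("no chromosome shared between CpGs and lncRNAs")
  cor_one <- function(meth, lnc, cset, lset) {
    shared <- intersect(colnames(meth$beta), colnames(lnc))
    b <- meth$beta[cset, shared, drop = FALSE]
    e <- unclass(lnc)[lset, shared, drop = FALSE]
    n <- length(shared)
    rb <- t(apply(b, 1L, rank, ties.method = "average"))
    re <- t(apply(e, 1L, rank, ties.method = "average"))
    rho <- suppressWarnings(stats::cor(t(rb), t(re)))
    rho_c <- pmin(pmax(rho, -1), 1)
    tstat <- rho_c * sqrt((n - 2) / pmax(1 - rho_c^2, .Machine$double.eps))
    p <- pmax(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    list(rho = rho, p = p)
  }
  all_pairs <- list()
  n_tests <- 0L
  for (ch in chroms) {
    cset <- cpgs[pos$chrom[match(cpgs, pos$cpg_id)] == ch]
    lset <- lncs[ann$chrom[match(lncs, ann$gene_id)] == ch]
    if (length(cset) == 0 || length(lset) == 0) next
    n_tests <- n_tests + length(cset) * length(lset)
    a <- cor_one(methA, lncA, cset, lset)
    b <- cor_one(methB, lncB, cset, lset)
    idx <- which(!is.na(a$rho), arr.ind = TRUE)
    all_pairs[[ch]] <- data.frame(
      cpg_id = cset[idx[, 1]], lnc_id = lset[idx[, 2]], chrom = ch,
      rho_A = a$rho[idx], p_A = a$p[idx], rho_B = b$rho[idx], p_B = b$p[idx],
      stringsAsFactors = FALSE)
  }
  if (n_tests == 0) stop("zero same-chromosome pairs")
  tab <- do.call(rbind, c(all_pairs, list(make.row.names = FALSE)))
  sig <- tab$p_A * n_tests < alpha & tab$p_B * n_tests < alpha
  agree <- sign(tab$rho_A) == sign(tab$rho_B) & sign(tab$rho_A) != 0
  kept_any <- tab[sig & agree, , drop = FALSE]
  kept <- switch(direction,
                 negative = kept_any[kept_any$rho_A < 0, , drop = FALSE],
                 positive = kept_any[kept_any$rho_A > 0, , drop = FALSE],
                 both = kept_any)
  cpg_pos <- methA$positions$pos[match(kept$cpg_id, methA$positions$cpg_id)]
  tss <- annot$tss[match(kept$lnc_id, annot$gene_id)]
  kept$distance_bp <- abs(cpg_pos - tss)
  rownames(kept) <- NULL
  list(pairs = kept, n_tests = n_tests, n_kept_any_sign = nrow(kept_any))
}

#' Chromatin-state enrichment of a CpG set
#'
#' CpGs are assigned to states by point-in-interval; upper-tail
#' hypergeometric per state against the full CpG manifest as background,
#' BH-adjusted.
#'
#' @param cpg_ids CpGs of interest.
#' @param positions data.frame cpg_id, chrom, pos covering background.
#' @param segmentation SegmentationTrack.
#' @param background character vector of all manifest CpG ids.
#' @return [hypergeom_enrich()] table.
#' @export
cpg_context_enrichment <- function(cpg_ids, positions, segmentation, background) {
  miss <- setdiff(background, positions$cpg_id)
  if (length(miss)) stop("CpG(s) without position: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  pos <- positions[match(background, positions$cpg_id), ]
  gr <- pos_to_gr(pos$chrom, pos$pos)
  segs <- segmentation$segments
  ov <- GenomicRanges::findOverlaps(gr, gi_to_gr(segs))
  by_state <- split(background[S4Vectors::queryHits(ov)],
                    segs$label[S4Vectors::subjectHits(ov)])
  hypergeom_enrich(query = cpg_ids, terms = by_state, universe = background)
}

#' ATAC accessibility contrast at CpG-containing peaks
#'
#' Per sample, the mean normalized signal over peaks containing (point-in-
#' interval) any of the supplied CpGs; ER+ vs ER- Wilcoxon rank-sum.
#'
#' @param cpg_ids CpGs of interest.
#' @param positions data.frame cpg_id, chrom, pos.
#' @param atac ATACMatrix.
#' @param clin ClinicalTable with er_status for the ATAC samples.
#' @return list with `sample_means`, `p`, `n_peaks`.
#' @export
cpg_atac_contrast <- function(cpg_ids, positions, atac, clin) {
  pos <- positions[match(cpg_ids, positions$cpg_id), ]
  if (any(is.na(pos$pos))) stop("CpG(s) without position")
  hits <- IRanges::overlapsAny(gi_to_gr(atac$peaks), pos_to_gr(pos$chrom, pos$pos))
  if (!any(hits)) stop("no peak contains any of the CpGs")
  means <- colMeans(atac$signal[hits, , drop = FALSE])
  er <- clin$er_status[match(names(means), clin$sample_id)]
  xs <- means[!is.na(er) & er == "pos"]
  ys <- means[!is.na(er) & er == "neg"]
  if (length(xs) == 0 || length(ys) == 0) stop("need samples in both ER groups")
  list(sample_means = means, p = wilcoxon_ranksum(xs, ys)$p, n_peaks = sum(hits))
}

#' Flag CpG-lncRNA pairs supported by chromatin loops
#'
#' A pair is loop-supported iff some loop has the CpG position inside one
#' foot and the lncRNA TSS inside the other foot; co-location in the same
#' foot does not count.
#'
#' @param pairs data.frame with cpg_id, lnc_id (e.g. from [cis_correlation()]).
#' @param positions data.frame cpg_id, chrom, pos.
#' @param loops LoopSet.
#' @param annot GeneAnnotation giving lncRNA chrom and TSS.
#' @return `pairs` with a logical `loop_supported` column.
#' @export
loop_support <- function(pairs, positions, loops, annot) {
  pairs$loop_supported <- FALSE
  if (nrow(pairs) == 0 || nrow(loops) == 0) return(pairs)
  cpos <- positions[match(pairs$cpg_id, positions$cpg_id), ]
  tss <- annot$tss[match(pairs$lnc_id, annot$gene_id)]
  tchrom <- annot$chrom[match(pairs$lnc_id, annot$gene_id)]
  in_foot <- function(chrom, p, fchrom, fstart, fend)
    chrom == fchrom & p >= fstart & p < fend
  for (i in seq_len(nrow(pairs))) {
    c_in1 <- in_foot(cpos$chrom[i], cpos$pos[i], loops$chrom1, loops$start1, loops$end1)
    c_in2 <- in_foot(cpos$chrom[i], cpos$pos[i], loops$chrom2, loops$start2, loops$end2)
    t_in1 <- in_foot(tchrom[i], tss[i], loops$chrom1, loops$start1, loops$end1)
    t_in2 <- in_foot(tchrom[i], tss[i], loops$chrom2, loops$start2, loops$end2)
    pairs$loop_supported[i] <- any((c_in1 & t_in2) | (c_in2 & t_in1))
  }
  pairs
}

#' Flag gene pairs joined by chromatin loops (gene-body overlap)
#'
#' The gene-body analogue of [loop_support()]: two genes are loop-joined iff
#' their bodies intersect two different feet of the same loop.
#'
#' @param gene_pairs data.frame with columns `gene1`, `gene2`.
#' @param loops LoopSet.
#' @param annot GeneAnnotation with both genes' bodies.
#' @return `gene_pairs` with a logical `loop_supported` column.
#' @export
loop_support_genes <- function(gene_pairs, loops, annot) {
  gene_pairs$loop_supported <- FALSE
  if (nrow(gene_pairs) == 0 || nrow(loops) == 0) return(gene_pairs)
  g1 <- annot[match(gene_pairs$gene1, annot$gene_id), ]
  g2 <- annot[match(gene_pairs$gene2, annot$gene_id), ]
  olap <- function(chrom, s, e, fchrom, fs, fe)
    chrom == fchrom & s < fe & fs < e
  for (i in seq_len(nrow(gene_pairs))) {
    a1 <- olap(g1$chrom[i], g1$start[i], g1$end[i], loops$chrom1, loops$start1, loops$end1)
    a2 <- olap(g1$chrom[i], g1$start[i], g1$end[i], loops$chrom2, loops$start2, loops$end2)
    b1 <- olap(g2$chrom[i], g2$start[i], g2$end[i], loops$chrom1, loops$start1, loops$end1)
    b2 <- olap(g2$chrom[i], g2$start[i], g2$end[i], loops$chrom2, loops$start2, loops$end2)
    gene_pairs$loop_supported[i] <- any((a1 & b2) | (a2 & b1))
  }
  gene_pairs
}
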