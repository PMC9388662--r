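# Promoter-centric regulatory characterization: strand-aware promoter
# windows, independence against padded protein-coding loci, nearest-gene
# assignment, ATAC accessibility contrasts by ER status, and chromHMM / TFBS
# enrichment. Interval arithmetic is delegated to GenomicRanges; all
# coordinates entering and leaving these functions are 0-based half-open.

#' Strand-aware promoter windows around lncRNA TSSs
#'
#' On the + strand the window is `[tss - upstream, tss + downstream)`; on the
#' - strand `[tss - downstream + 1, tss + upstream + 1)`. Both have length
#' upstream + downstream and contain the TSS base. Windows are truncated at
#' chromosome bounds (with a warning) when `chrom_sizes` is supplied.
#'
#' @param annot GeneAnnotation (lncRNA rows are used).
#' @param upstream,downstream window extents in bp (5' / 3' of the TSS).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return data.frame of class `PromoterSet`: lnc_id, chrom, start, end,
#'   strand, tss.
#' @export
promoter_windows <- function(annot, upstream = 200, downstream = 100,
                             chrom_sizes = NULL) {
  lnc <- annot[annot$biotype == "lncRNA", , drop = FALSE]
  pos <- lnc$strand == "+"
  start <- ifelse(pos, lnc$tss - upstream, lnc$tss - downstream + 1L)
  end <- ifelse(pos, lnc$tss + downstream, lnc$tss + upstream + 1L)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[lnc$chrom]
    if (any(lnc$tss < 0 | lnc$tss >= lim)) stop("TSS outside chromosome bounds")
    if (any(start < 0 | end > lim)) warning("promoter window(s) truncated at chromosome bounds")
    start <- pmax(start, 0L)
    end <- pmin(end, lim)
  } else if (any(start < 0)) {
    warning("promoter window(s) truncated at position 0")
    start <- pmax(start, 0L)
  }
  structure(data.frame(lnc_id = lnc$gene_id, chrom = lnc$chrom,
                       start = as.integer(start), end = as.integer(end),
                       strand = lnc$strand, tss = lnc$tss,
                       stringsAsFactors = FALSE),
            class = c("PromoterSet", "data.frame"))
}

promoters_to_gr <- function(prom) {
  GenomicRanges::GRanges(prom$chrom, IRanges::IRanges(prom$start + 1L, prom$end))
}

#' Classify promoters as independent of protein-coding loci
#'
#' Protein-coding loci are padded upstream (strand-aware, `pad_upstream` bp
#' 5' of the gene) and any >= 1 bp intersection of a promoter with any padded
#' locus marks it `overlapping`; all remaining promoters are `independent`.
#'
#' @param prom PromoterSet.
#' @param pc_annot GeneAnnotation (protein-coding rows are used).
#' @param pad_upstream padding added 5' of each protein-coding gene.
#' @param strand_aware pad on the annotated 5' end (TRUE) or always on the
#'   left/lower coordinate (FALSE).
#' @return PromoterSet with a logical `independent` column.
#' @export
classify_independent <- function(prom, pc_annot, pad_upstream = 200,
                                 strand_aware = TRUE) {
  if (pad_upstream < 0) stop("pad_upstream must be >= 0")
  pc <- pc_annot[pc_annot$biotype == "protein_coding", , drop = FALSE]
  if (nrow(pc) == 0) {
    prom$independent <- TRUE
    return(prom)
  }
  if (strand_aware) {
    pstart <- ifelse(pc$strand == "+", pc$start - pad_upstream, pc$start)
    pend <- ifelse(pc$strand == "+", pc$end, pc$end + pad_upstream)
  } else {
    pstart <- pc$start - pad_upstream
    pend <- pc$end
  }
  pstart <- pmax(pstart, 0)
  loci <- GenomicRanges::GRanges(pc$chrom, IRanges::IRanges(pstart + 1L, pend))
  hit <- IRanges::overlapsAny(promoters_to_gr(prom), loci)
  prom$independent <- !hit
  prom
}

#' Nearest protein-coding gene for each promoter
#'
#' Minimal genomic distance between the promoter interval and the gene body
#' (0 when they overlap); equidistant candidates are broken by the smaller
#' gene start. The reported distance is signed: negative when the
#' protein-coding gene lies upstream (lower coordinates) of the promoter on
#' the + reference orientation.
#'
#' @param prom PromoterSet (typically the independent subset).
#' @param pc_annot GeneAnnotation.
#' @return data.frame: lnc_id, nearest_pc_gene, distance (signed bp; NA when
#'   the promoter's chromosome has no protein-coding gene).
#' @export
nearest_pc_gene <- function(prom, pc_annot) {
  pc <- pc_annot[pc_annot$biotype == "protein_coding", , drop = FALSE]
  res <- data.frame(lnc_id = prom$lnc_id, nearest_pc_gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(prom))) {
    cand <- pc[pc$chrom == prom$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    # gap between [s1,e1) and [s2,e2): 0 if they intersect
    gap <- pmax(cand$start - prom$end[i], prom$start[i] - cand$end, 0)
    best <- which(gap == min(gap))
    if (length(best) > 1) best <- best[which.min(cand$start[best])]
    sgn <- if (gap[best] == 0) 1 else if (cand$end[best] <= prom$start[i]) -1 else 1
    res$nearest_pc_gene[i] <- cand$gene_id[best]
    res$distance[i] <- sgn * gap[best]
  }
  if (any(is.na(res$nearest_pc_gene)))
    warning("promoter(s) on chromosome(s) without protein-coding genes")
  res
}

#' ATAC accessibility contrast at promoter-containing peaks
#'
#' A peak "contains" a promoter when they intersect by >= 1 bp. Per sample,
#' the mean normalized signal over all such peaks is computed, and ER+ vs ER-
#' samples are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param atac ATACMatrix.
#' @param prom PromoterSet subset of interest (e.g. ER+-associated promoters).
#' @param clin ClinicalTable with `er_status` covering the ATAC samples.
#' @return list with `sample_means` (named vector), `p` (Wilcoxon), `n_peaks`.
#' @export
atac_promoter_contrast <- function(atac, prom, clin) {
  hits <- IRanges::overlapsAny(gi_to_gr(atac$peaks), promoters_to_gr(prom))
  if (!any(hits)) stop("no peak overlaps the promoter set")
  means <- colMeans(atac$signal[hits, , drop = FALSE])
  er <- clin$er_status[match(names(means), clin$sample_id)]
  xs <- means[!is.na(er) & er == "pos"]
  ys <- means[!is.na(er) & er == "neg"]
  if (length(xs) == 0 || length(ys) == 0) stop("need samples in both ER groups")
  list(sample_means = means, p = wilcoxon_ranksum(xs, ys)$p, n_peaks = sum(hits))
}

# promoters -> states they intersect (multi-label); returns list promoter -> states
.promoter_states <- function(prom, segments) {
  ov <- GenomicRanges::findOverlaps(promoters_to_gr(prom), gi_to_gr(segments))
  split(segments$label[S4Vectors::subjectHits(ov)],
        factor(prom$lnc_id[S4Vectors::queryHits(ov)], levels = prom$lnc_id))
}

#' chromHMM state enrichment of a promoter subset
#'
#' A promoter supports a state when it intersects >= 1 bp of a segment with
#' that label (multi-label: one promoter can support several states). Each
#' state is tested with the upper-tail hypergeometric against the full
#' promoter set as universe; states supported by < `min_support` query
#' promoters are excluded, and p-values are BH-adjusted.
#'
#' @param query_prom promoter subset of interest.
#' @param segmentation SegmentationTrack.
#' @param all_prom background promoter set (universe).
#' @param min_support minimum query support per state.
#' @return [hypergeom_enrich()] table with a `cell_line` column.
#' @export
chromhmm_promoter_enrichment <- function(query_prom, segmentation, all_prom,
                                         min_support = 10) {
  segs <- segmentation$segments
  bad <- setdiff(unique(segs$label), CHROMHMM_STATES)
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  states_by_prom <- .promoter_states(all_prom, segs)
  terms <- lapply(stats::setNames(nm = CHROMHMM_STATES), function(st) {
    names(states_by_prom)[vapply(states_by_prom, function(s) st %in% s, TRUE)]
  })
  terms <- terms[vapply(terms, length, 0L) > 0]
  res <- hypergeom_enrich(query = query_prom$lnc_id, terms = terms,
                          universe = all_prom$lnc_id, min_support = min_support)
  if (nrow(res)) res$cell_line <- segmentation$cell_line
  res
}

#' TFBS-set enrichment of a promoter subset (Fisher exact)
#'
#' Per TFBS set, the 2x2 table (subset & hit, subset & miss, rest & hit,
#' rest & miss) where "hit" means the promoter intersects >= 1 site of the
#' set by >= 1 bp; one-sided (greater) Fisher exact p, BH-adjusted across
#' sets. A TF may contribute several sets; each is reported separately.
#'
#' @param query_prom promoter subset of interest.
#' @param tfbs TFBSCollection.
#' @param all_prom background promoter universe (must contain the subset).
#' @return data.frame: set_id, n_hit_query, n_query, n_hit_rest, n_rest,
#'   odds_ratio, p, p_adj.
#' @export
tfbs_promoter_enrichment <- function(query_prom, tfbs, all_prom) {
  if (!all(query_prom$lnc_id %in% all_prom$lnc_id))
    stop("query promoters must be contained in the universe")
  in_query <- all_prom$lnc_id %in% query_prom$lnc_id
  gr_all <- promoters_to_gr(all_prom)
  rows <- lapply(names(tfbs), function(sid) {
    sites <- tfbs[[sid]]
    if (nrow(sites) == 0) {
      warning("skipping empty TFBS set ", sid)
      return(NULL)
    }
    hit <- IRanges::overlapsAny(gr_all, gi_to_gr(sites))
    a <- sum(hit & in_query); b <- sum(!hit & in_query)
    c_ <- sum(hit & !in_query); d <- sum(!hit & !in_query)
    ft <- fisher_exact_2x2(a, b, c_, d, alternative = "greater")
    data.frame(set_id = sid, n_hit_query = a, n_query = a + b,
               n_hit_rest = c_, n_rest = c_ + d,
               odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable TFBS sets")
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
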