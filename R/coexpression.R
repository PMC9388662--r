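# The replicated lncRNA x mRNA co-expression engine: Spearman correlation of
# every lncRNA against every mRNA in two cohorts, Bonferroni-replicated edge
# calls, degree and |rho| filtering, +/-1 binarization and 3x3 hierarchical
# biclustering with clinical annotation of the lncRNA clusters.

#' All-pairs Spearman correlation between two expression matrices
#'
#' Ranks each gene across the shared samples (average ranks for ties),
#' computes the full lncRNA x mRNA Pearson correlation of ranks, and derives
#' p-values from the t approximation on n - 2 degrees of freedom. Genes with
#' constant expression yield NA correlations (excluded from the test count)
#' with a warning.
#'
#' @param lnc_expr,mrna_expr ExpressionMatrix objects (log2p1) sharing sample ids.
#' @return list with `rho` and `p` matrices (lncRNAs x mRNAs) and `n_samples`.
#' @export
spearman_pair_matrix <- function(lnc_expr, mrna_expr) {
  shared <- intersect(colnames(lnc_expr), colnames(mrna_expr))
  if (length(shared) < 10) stop("need >= 10 shared samples")
  a <- unclass(lnc_expr)[, shared, drop = FALSE]
  b <- unclass(mrna_expr)[, shared, drop = FALSE]
  n <- length(shared)
  const_a <- apply(a, 1L, function(v) length(unique(v)) == 1)
  const_b <- apply(b, 1L, function(v) length(unique(v)) == 1)
  if (any(const_a) || any(const_b))
    warning("constant gene vector(s); their correlations are NA")
  ra <- t(apply(a, 1L, rank, ties.method = "average"))
  rb <- t(apply(b, 1L, rank, ties.method = "average"))
  rho <- suppressWarnings(stats::cor(t(ra), t(rb)))
  rho[const_a, ] <- NA_real_
  rho[, const_b] <- NA_real_
  rho_c <- pmin(pmax(rho, -1), 1)
  tstat <- rho_c * sqrt((n - 2) / pmax(1 - rho_c^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  p[is.na(rho)] <- NA_real_
  dimnames(rho) <- dimnames(p) <- list(rownames(a), rownames(b))
  list(rho = rho, p = p, n_samples = n)
}

#' Bonferroni-replicated correlation edges across two cohorts
#'
#' An edge (lncRNA, mRNA) is kept iff its Bonferroni-corrected p-value
#' (p * n_tests, n_tests = non-NA pairs per cohort) is strictly below `alpha`
#' in BOTH cohorts and the correlation signs agree; significant pairs with
#' conflicting signs are dropped and counted.
#'
#' @param corA,corB results of [spearman_pair_matrix()] per cohort.
#' @param alpha family-wise threshold.
#' @return list of class `CorrelationEdgeSet`: `edges` data.frame (lnc_id,
#'   mrna_id, rho_A, p_A, rho_B, p_B, sign), `n_tests_A`, `n_tests_B`,
#'   `n_sign_conflict`.
#' @export
bonferroni_replicated_edges <- function(corA, corB, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!identical(dimnames(corA$rho), dimnames(corB$rho)))
    stop("cohort pair universes differ")
  nA <- sum(!is.na(corA$p)); nB <- sum(!is.na(corB$p))
  sigA <- !is.na(corA$p) & corA$p * nA < alpha
  sigB <- !is.na(corB$p) & corB$p * nB < alpha
  both <- sigA & sigB
  agree <- sign(corA$rho) == sign(corB$rho) & sign(corA$rho) != 0
  conflict <- sum(both & !agree, na.rm = TRUE)
  keep <- which(both & agree, arr.ind = TRUE)
  edges <- data.frame(
    lnc_id = rownames(corA$rho)[keep[, 1]],
    mrna_id = colnames(corA$rho)[keep[, 2]],
    rho_A = corA$rho[keep], p_A = corA$p[keep],
    rho_B = corB$rho[keep], p_B = corB$p[keep],
    sign = ifelse(corA$rho[keep] > 0, "+", "-"),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, n_tests_A = nA, n_tests_B = nB,
                 n_sign_conflict = conflict),
            class = "CorrelationEdgeSet")
}

#' Degree and correlation-strength filtering of the edge set
#'
#' Degrees (numbers of replicated edges) are computed on the full replicated
#' edge set; lncRNAs (mRNAs) with degree strictly above the mean lncRNA
#' (mRNA) degree are retained, and edges between retained genes are then
#' required to satisfy |rho| > `rho_min` in both cohorts.
#'
#' @param edge_set CorrelationEdgeSet.
#' @param rho_min correlation magnitude threshold.
#' @return list with `edges` (filtered data.frame), `lnc_retained`,
#'   `mrna_retained`, `mean_lnc_degree`, `mean_mrna_degree`.
#' @export
degree_and_rho_filter <- function(edge_set, rho_min = 0.4) {
  edges <- edge_set$edges
  if (nrow(edges) == 0) stop("empty edge set")
  lnc_deg <- table(edges$lnc_id)
  mrna_deg <- table(edges$mrna_id)
  mean_lnc <- mean(lnc_deg)
  mean_mrna <- mean(mrna_deg)
  lnc_keep <- names(lnc_deg)[lnc_deg > mean_lnc]
  mrna_keep <- names(mrna_deg)[mrna_deg > mean_mrna]
  if (length(lnc_keep) == 0 || length(mrna_keep) == 0)
    warning("all degrees equal on one side; retained set is empty")
  sel <- edges$lnc_id %in% lnc_keep & edges$mrna_id %in% mrna_keep &
    abs(edges$rho_A) > rho_min & abs(edges$rho_B) > rho_min
  list(edges = edges[sel, , drop = FALSE],
       lnc_retained = lnc_keep, mrna_retained = mrna_keep,
       mean_lnc_degree = mean_lnc, mean_mrna_degree = mean_mrna)
}

# deterministic leaf-order hclust on 1 - Pearson rows of a matrix
.hclust_correlation <- function(m, method = "average") {
  d <- stats::as.dist(1 - suppressWarnings(stats::cor(t(m))))
  stats::hclust(d, method = method)
}

#' Binarize the filtered edge set and bicluster it
#'
#' Builds the lncRNA x mRNA relation matrix with +1/-1 for retained positive/
#' negative edges and 0 elsewhere, removes all-zero rows/columns, clusters
#' rows and columns independently (average linkage on 1 - Pearson distance of
#' the binarized profiles) and cuts each tree into exactly `k` clusters.
#' Cluster labels are reassigned by descending cluster size (rows: 1..k,
#' columns: A..).
#'
#' @param filtered result of [degree_and_rho_filter()].
#' @param k_rows,k_cols number of lncRNA / mRNA clusters.
#' @return list of class `BiclusterResult`: `matrix` (binarized), `lnc_labels`
#'   (named integer), `mrna_labels` (named character A/B/C...),
#'   `row_hclust`, `col_hclust`.
#' @export
binarize_bicluster <- function(filtered, k_rows = 3, k_cols = 3) {
  edges <- filtered$edges
  lncs <- sort(unique(edges$lnc_id))
  mrnas <- sort(unique(edges$mrna_id))
  if (length(lncs) < k_rows || length(mrnas) < k_cols)
    stop("not enough genes to cut ", k_rows, "x", k_cols, " clusters")
  M <- matrix(0, length(lncs), length(mrnas), dimnames = list(lncs, mrnas))
  M[cbind(match(edges$lnc_id, lncs), match(edges$mrna_id, mrnas))] <-
    ifelse(edges$sign == "+", 1, -1)
  rz <- rowSums(M != 0) == 0
  cz <- colSums(M != 0) == 0
  if (any(rz) || any(cz)) {
    warning("removing all-zero rows/columns before clustering")
    M <- M[!rz, !cz, drop = FALSE]
  }
  # zero-variance binarized profiles carry no clustering signal either
  rv <- apply(M, 1L, stats::sd) == 0
  cv <- apply(M, 2L, stats::sd) == 0
  if (any(rv) || any(cv)) {
    warning("removing zero-variance profiles before clustering")
    M <- M[!rv, !cv, drop = FALSE]
  }
  if (nrow(M) < k_rows || ncol(M) < k_cols)
    stop("fewer than k rows/columns remain after removal")
  rhc <- .hclust_correlation(M)
  chc <- .hclust_correlation(t(M))
  rcut <- stats::cutree(rhc, k = k_rows)
  ccut <- stats::cutree(chc, k = k_cols)
  relabel <- function(cut) {
    sizes <- sort(table(cut), decreasing = TRUE)
    map <- stats::setNames(seq_along(sizes), names(sizes))
    unname(map[as.character(cut)])
  }
  lnc_labels <- stats::setNames(relabel(rcut), names(rcut))
  mrna_num <- relabel(ccut)
  mrna_labels <- stats::setNames(LETTERS[mrna_num], names(ccut))
  structure(list(matrix = M, lnc_labels = lnc_labels, mrna_labels = mrna_labels,
                 row_hclust = rhc, col_hclust = chc),
            class = "BiclusterResult")
}

#' Annotate lncRNA clusters with differential-expression consensus calls
#'
#' For each lncRNA cluster and each consensus table, the fraction of member
#' lncRNAs replicated-overexpressed in each group of the contrast.
#'
#' @param lnc_labels named cluster vector from [binarize_bicluster()].
#' @param consensus_tables named list of [cross_cohort_consensus()] results.
#' @return data.frame: cluster, contrast, frac_up_g1, frac_up_g2, frac_unannotated.
#' @export
annotate_clusters <- function(lnc_labels, consensus_tables) {
  rows <- list()
  for (cl in sort(unique(lnc_labels))) {
    members <- names(lnc_labels)[lnc_labels == cl]
    for (ctr in names(consensus_tables)) {
      tab <- consensus_tables[[ctr]]$table
      st <- tab$status[match(members, tab$gene_id)]
      st[is.na(st)] <- "unannotated"
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, contrast = ctr, n_members = length(members),
        frac_up_g1 = mean(st == "replicated_up_g1"),
        frac_up_g2 = mean(st == "replicated_up_g2"),
        frac_unannotated = mean(st == "unannotated"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, approximately 0 for independent ones.
#'
#' @param a,b label vectors over the same items (matched by name when named).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
  }
  if (length(a) != length(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
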