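# Cell-type attribution of lncRNA clusters: signature scores for lymphocyte /
# fibroblast infiltration, per-lncRNA multivariate linear models against the
# three candidate drivers (ESR1 expression, fibroblast score, lymphocyte
# score), cluster-level coefficient comparison, and single-cell verification
# summaries.

#' Mean-expression signature score per sample
#'
#' The unweighted mean of log2(TPM+1) expression over the signature genes
#' present in the matrix; used as the in-silico infiltration estimate.
#'
#' @param expr ExpressionMatrix in log2p1.
#' @param gene_set character vector of signature gene ids.
#' @return list with `score` (named per-sample vector) and `coverage`
#'   (fraction of the set present in the matrix).
#' @export
signature_score <- function(expr, gene_set) {
  stopifnot_unit(expr, "log2p1")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) stop("no signature gene present in the matrix")
  list(score = colMeans(unclass(expr)[present, , drop = FALSE]),
       coverage = length(present) / length(unique(gene_set)))
}

#' Per-lncRNA attribution to ESR1 / fibroblast / lymphocyte drivers
#'
#' Fits, for every lncRNA, the ordinary least-squares model
#' expression ~ ESR1 + fibroblast + lymphocyte with all three predictors
#' z-standardized so coefficients are comparable across variables. The
#' best-explaining variable is the one with the smallest coefficient p-value
#' (ties broken by largest |t|).
#'
#' @param lnc_expr ExpressionMatrix (log2p1), lncRNAs x samples.
#' @param esr1 numeric ESR1 expression per sample.
#' @param fib_score,lym_score numeric per-sample infiltration scores.
#' @return data.frame: lnc_id, coef_esr1, coef_fib, coef_lym, p_esr1, p_fib,
#'   p_lym, best_variable.
#' @export
glm_attribution <- function(lnc_expr, esr1, fib_score, lym_score) {
  stopifnot_unit(lnc_expr, "log2p1")
  n <- ncol(lnc_expr)
  if (n < 10) stop("need >= 10 samples")
  preds <- cbind(ESR1 = esr1, fibroblast = fib_score, lymphocyte = lym_score)
  if (nrow(preds) != n) stop("predictor length mismatch")
  sds <- apply(preds, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant predictor(s): ", paste(colnames(preds)[sds == 0], collapse = ", "))
  Z <- scale(preds)
  cc <- stats::cor(Z)
  hi <- which(abs(cc) > 0.99 & row(cc) < col(cc), arr.ind = TRUE)
  if (nrow(hi)) {
    if (any(abs(cc[hi]) >= 1 - 1e-12))
      stop("exactly collinear predictors: ",
           paste(colnames(Z)[hi[1, ]], collapse = " ~ "))
    warning("near-collinear predictors (|r| > 0.99)")
  }
  X <- cbind(1, Z)
  XtX_inv <- solve(crossprod(X))
  H <- XtX_inv %*% t(X)
  Y <- t(unclass(lnc_expr))          # samples x genes
  B <- H %*% Y                       # 4 x genes coefficient matrix
  fitted <- X %*% B
  rss <- colSums((Y - fitted)^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  se <- sqrt(outer(diag(XtX_inv), sigma2))
  tmat <- B / se
  pmat <- 2 * stats::pt(-abs(tmat), df = df)
  vars <- c("ESR1", "fibroblast", "lymphocyte")
  pick <- vapply(seq_len(ncol(B)), function(j) {
    p3 <- pmat[2:4, j]; t3 <- abs(tmat[2:4, j])
    cand <- which(p3 == min(p3))
    if (length(cand) > 1) cand <- cand[which.max(t3[cand])]
    cand
  }, integer(1))
  data.frame(lnc_id = rownames(lnc_expr),
             coef_esr1 = B[2, ], coef_fib = B[3, ], coef_lym = B[4, ],
             p_esr1 = pmat[2, ], p_fib = pmat[3, ], p_lym = pmat[4, ],
             best_variable = vars[pick],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare attribution coefficients across lncRNA clusters
#'
#' For each of the three coefficient vectors, a Kruskal-Wallis test across
#' clusters (clusters with < 3 members are excluded with a warning), plus the
#' per-cluster fractions of members assigned to each best variable.
#'
#' @param attribution result of [glm_attribution()].
#' @param lnc_labels named cluster vector.
#' @return list with `kw` (data.frame variable, H, p) and `fractions`
#'   (data.frame cluster, n, frac_esr1, frac_fib, frac_lym).
#' @export
compare_cluster_coefficients <- function(attribution, lnc_labels) {
  shared <- intersect(attribution$lnc_id, names(lnc_labels))
  att <- attribution[match(shared, attribution$lnc_id), ]
  lab <- lnc_labels[shared]
  counts <- table(lab)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("excluding cluster(s) with < 3 members: ", paste(small, collapse = ", "))
    keep <- !(lab %in% small)
    att <- att[keep, ]; lab <- lab[keep]
  }
  if (length(unique(lab)) < 2) stop("need >= 2 clusters with >= 3 members")
  kw <- do.call(rbind, lapply(
    c(ESR1 = "coef_esr1", fibroblast = "coef_fib", lymphocyte = "coef_lym"),
    function(col) {
      res <- kruskal_wallis(split(att[[col]], lab))
      data.frame(H = res$H, p = res$p)
    }))
  kw <- data.frame(variable = c("ESR1", "fibroblast", "lymphocyte"), kw,
                   row.names = NULL)
  fractions <- do.call(rbind, lapply(sort(unique(lab)), function(cl) {
    bv <- att$best_variable[lab == cl]
    data.frame(cluster = cl, n = length(bv),
               frac_esr1 = mean(bv == "ESR1"),
               frac_fib = mean(bv == "fibroblast"),
               frac_lym = mean(bv == "lymphocyte"))
  }))
  list(kw = kw, fractions = fractions)
}

#' Log-normalize single-cell counts
#'
#' Per cell: x -> ln(1 + x * scale_factor / cell_total). Cells with zero
#' total counts are removed with a warning.
#'
#' @param sc SingleCellDataset.
#' @param scale_factor library-size scale factor.
#' @return list with `norm` (dense matrix, genes x cells) and `cell_type`.
#' @export
sc_lognormalize <- function(sc, scale_factor = 10000) {
  counts <- as.matrix(sc$counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning("removing ", sum(totals == 0), " cell(s) with zero total counts")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- log1p(sweep(counts, 2L, totals / scale_factor, "/"))
  list(norm = norm, cell_type = sc$cell_type[colnames(norm)])
}

#' Dot-plot summary of genes across cell types
#'
#' Per gene x cell type: the percentage of cells of the type with a nonzero
#' count and the mean normalized expression over those cells' compartment.
#'
#' @param sc SingleCellDataset (for raw counts / expression detection).
#' @param normalized result of [sc_lognormalize()].
#' @param genes genes to summarize (must be present).
#' @return data.frame: gene_id, cell_type, pct_expressing, mean_norm_expr.
#' @export
dotplot_summary <- function(sc, normalized, genes) {
  miss <- setdiff(genes, rownames(sc$counts))
  if (length(miss)) stop("genes absent from the dataset: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  counts <- as.matrix(sc$counts)[genes, colnames(normalized$norm), drop = FALSE]
  types <- unique(normalized$cell_type)
  rows <- list()
  for (ty in types) {
    cells <- names(normalized$cell_type)[normalized$cell_type == ty]
    if (length(cells) == 0) next
    pct <- 100 * rowMeans(counts[, cells, drop = FALSE] > 0)
    mn <- rowMeans(normalized$norm[genes, cells, drop = FALSE])
    rows[[ty]] <- data.frame(gene_id = genes, cell_type = ty,
                             pct_expressing = unname(pct),
                             mean_norm_expr = unname(mn),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' One-vs-rest Wilcoxon marker test
#'
#' For every group, each gene is tested (rank-sum, two-sided) between the
#' group's samples and all others on the supplied expression values, with BH
#' adjustment across genes within the group; logFC is the mean difference.
#'
#' @param expr numeric genes x samples matrix (normalized expression).
#' @param group_labels vector of group labels over samples (>= 2 groups,
#'   every group >= 2 members).
#' @return data.frame: group, gene_id, logFC, p, p_adj.
#' @export
marker_test_one_vs_rest <- function(expr, group_labels) {
  group_labels <- as.character(group_labels)
  lev <- sort(unique(group_labels))
  if (length(lev) < 2) stop("need >= 2 groups")
  if (any(table(group_labels) < 2)) stop("every group needs >= 2 members")
  out <- list()
  for (g in lev) {
    ing <- group_labels == g
    res <- lapply(rownames(expr), function(gene) {
      x <- expr[gene, ing]; y <- expr[gene, !ing]
      p <- if (stats::sd(c(x, y)) == 0) 1 else wilcoxon_ranksum(x, y)$p
      data.frame(group = g, gene_id = gene, logFC = mean(x) - mean(y), p = p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, res)
    tab$p_adj <- bh_adjust(pmax(tab$p, .Machine$double.xmin))
    out[[g]] <- tab
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
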