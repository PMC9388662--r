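# Gene filtering and transformation applied to every cohort before analysis:
# expressed (> 1 TPM in > 5% of samples), variable (IQR of log2(TPM+1) > 0.1),
# plus the sample-level hierarchical clustering view.

#' Filter genes by minimum TPM prevalence
#'
#' A gene is retained iff strictly more than `min_fraction` of samples express
#' it strictly above `min_tpm` TPM. Both inequalities are strict.
#'
#' @param expr ExpressionMatrix in TPM.
#' @param min_tpm expression threshold (TPM).
#' @param min_fraction sample-fraction threshold.
#' @return character vector of retained gene ids (input order).
#' @export
tpm_expression_filter <- function(expr, min_tpm = 1, min_fraction = 0.05) {
  stopifnot_unit(expr, "TPM")
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  frac <- rowMeans(unclass(expr) > min_tpm)
  rownames(expr)[frac > min_fraction]
}

#' Filter genes by interquartile range
#'
#' IQR is the 75th minus the 25th percentile computed with the linear
#' order-statistic interpolation rule (R's default quantile type 7). A gene is
#' retained iff its IQR is strictly greater than `threshold`.
#'
#' @param expr ExpressionMatrix in log2(TPM+1).
#' @param threshold IQR threshold.
#' @return character vector of retained gene ids.
#' @export
iqr_filter <- function(expr, threshold = 0.1) {
  stopifnot_unit(expr, "log2p1")
  if (ncol(expr) < 4) stop("IQR filter needs >= 4 samples")
  iqr <- apply(unclass(expr), 1L, stats::IQR, type = 7)
  rownames(expr)[iqr > threshold]
}

#' Log-transform TPM expression
#'
#' Elementwise log2(x + 1); maps 0 to 0 and is invertible.
#'
#' @param expr ExpressionMatrix in TPM.
#' @return ExpressionMatrix in log2p1.
#' @export
log2p1_transform <- function(expr) {
  stopifnot_unit(expr, "TPM")
  expression_matrix(log2(unclass(expr) + 1), unit = "log2p1")
}

#' Invert the log2(TPM+1) transform
#' @param expr ExpressionMatrix in log2p1.
#' @return ExpressionMatrix in TPM.
#' @export
log2p1_invert <- function(expr) {
  stopifnot_unit(expr, "log2p1")
  expression_matrix(2^unclass(expr) - 1, unit = "TPM")
}

#' Hierarchically cluster samples on correlation distance
#'
#' Genes are optionally z-scored per gene (the displayed-heatmap convention),
#' the distance between two samples is 1 - Pearson correlation of their gene
#' vectors, and agglomeration uses Ward.D2.
#'
#' @param expr ExpressionMatrix in log2p1, >= 3 samples.
#' @param scale z-score rows (genes) before computing distances.
#' @return list with `order` (sample ids in dendrogram leaf order) and
#'   `hclust` (the merge tree).
#' @export
cluster_samples <- function(expr, scale = TRUE) {
  stopifnot_unit(expr, "log2p1")
  if (ncol(expr) < 3) stop("need >= 3 samples to cluster")
  m <- unclass(expr)
  if (scale) {
    sds <- apply(m, 1L, stats::sd)
    keep <- sds > 0
    m <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) / sds[keep]
  }
  svar <- apply(m, 2L, stats::sd)
  if (any(svar == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[svar == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "ward.D2")
  list(order = colnames(m)[hc$order], hclust = hc)
}

#' Run both expression filters and report the funnel
#'
#' Applies the TPM prevalence filter on the TPM matrix, then the IQR filter on
#' log2(TPM+1) of the survivors; the two masks commute, so the result equals
#' intersecting masks computed on the full matrix.
#'
#' @param expr ExpressionMatrix in TPM.
#' @param min_tpm,min_fraction,iqr_threshold filter parameters.
#' @return list with `expr` (filtered log2p1 matrix) and `report`
#'   (n_input_genes, n_pass_tpm, n_pass_iqr, retained_gene_ids).
#' @export
prep_expression <- function(expr, min_tpm = 1, min_fraction = 0.05,
                            iqr_threshold = 0.1) {
  stopifnot_unit(expr, "TPM")
  pass_tpm <- tpm_expression_filter(expr, min_tpm, min_fraction)
  lg <- log2p1_transform(expr[pass_tpm, , drop = FALSE])
  pass_iqr <- iqr_filter(lg, iqr_threshold)
  list(expr = lg[pass_iqr, , drop = FALSE],
       report = list(n_input_genes = nrow(expr),
                     n_pass_tpm = length(pass_tpm),
                     n_pass_iqr = length(pass_iqr),
                     retained_gene_ids = pass_iqr))
}
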