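# ---- ExpressionMatrix ------------------------------------------------------

#' Construct an expression matrix container
#'
#' A thin wrapper around a numeric genes x samples matrix carrying an explicit
#' unit flag, so that every stage can assert it receives expression on the
#' scale it expects (raw TPM or log2(TPM + 1)).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param unit `"TPM"` or `"log2p1"`.
#' @return An object of class `ExpressionMatrix`: the matrix with a `unit`
#'   attribute, dimnames mandatory and unique.
#' @export
expression_matrix <- function(values, unit = c("TPM", "log2p1")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene (row) and sample (column) names are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative (unit ", unit, ")")
  structure(values, unit = unit, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

expr_unit <- function(x) attr(x, "unit")

stopifnot_unit <- function(x, unit) {
  if (!inherits(x, "ExpressionMatrix"))
    stop("expected an ExpressionMatrix")
  if (!identical(expr_unit(x), unit))
    stop("expected unit '", unit, "', got '", expr_unit(x), "'")
  invisible(x)
}

# subsetting keeps class/unit; drop is forced FALSE so a single gene stays a matrix
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  out <- unclass(x)
  attr(out, "unit") <- NULL
  out <- out[i, j, drop = FALSE]
  structure(out, unit = attr(x, "unit"),
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' Read a genes x samples expression TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path TSV file path.
#' @param unit declared unit of the stored values (`"TPM"` or `"log2p1"`).
#' @return [expression_matrix()] object.
#' @export
read_expression <- function(path, unit = c("TPM", "log2p1")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene id column plus >=1 sample")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value at row %d (gene %s), column %s",
                 bad[1, 1], gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(gene_ids, colnames(vals))
  expression_matrix(num, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' @param expr ExpressionMatrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- ClinicalTable ---------------------------------------------------------

#' Construct a clinical table
#'
#' @param df data.frame with columns `sample_id`, `er_status` ("pos"/"neg"/NA),
#'   `her2_status`, `pam50` (LumA/LumB/Her2/Basal/Normal/NA), `os_time` (days),
#'   `os_event` (0/1/NA).
#' @return validated data.frame of class `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "er_status", "her2_status", "pam50", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing clinical columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  chk_lv <- function(x, lv, nm) {
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) stop("invalid ", nm, " value(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  chk_lv(df$er_status, c("pos", "neg"), "er_status")
  chk_lv(df$her2_status, c("pos", "neg"), "her2_status")
  chk_lv(df$pam50, c("LumA", "LumB", "Her2", "Basal", "Normal"), "pam50")
  chk_lv(df$os_event, c(0, 1), "os_event")
  if (any(!is.na(df$os_time) & df$os_time < 0)) stop("negative os_time")
  if (any(!is.na(df$os_event) & df$os_event == 1 & is.na(df$os_time)))
    stop("os_event = 1 requires os_time")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read / write clinical TSV ("NA" token encodes missing)
#' @param path TSV path.
#' @rdname clinical_io
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = c(sample_id = "character"))
  clinical_table(df)
}

#' @param clin ClinicalTable.
#' @rdname clinical_io
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- GeneAnnotation --------------------------------------------------------

#' Construct a gene annotation table
#'
#' Coordinates are 0-based half-open throughout the package (BED convention).
#' The TSS is derived from the strand: `start` on `+`, `end - 1` on `-`.
#'
#' @param df data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   ("+"/"-"), `biotype` ("lncRNA"/"protein_coding"). A `tss` column is
#'   recomputed if absent.
#' @return data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in annotation")
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  if (any(df$start >= df$end)) stop("annotation requires start < end")
  if (!all(df$biotype %in% c("lncRNA", "protein_coding")))
    stop("biotype must be lncRNA or protein_coding")
  short <- df$biotype == "lncRNA" & (df$end - df$start) <= 200
  if (any(short))
    stop("lncRNA genes must be > 200 bp: ", paste(df$gene_id[short], collapse = ", "))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Import a gene annotation TSV with declared coordinate convention
#'
#' Ensembl/BioMart-style tables are 1-based inclusive; the internal model is
#' uniformly 0-based half-open. `convention = "1based"` (the default) converts
#' on import; gene length (end - start in internal coordinates) is preserved.
#'
#' @param path TSV with columns gene_id, chrom, start, end, strand, biotype.
#' @param convention `"1based"` (inclusive, Ensembl) or `"0based"` (half-open).
#' @return [gene_annotation()] object, 0-based half-open.
#' @export
read_annotation <- function(path, convention = c("1based", "0based")) {
  convention <- match.arg(convention)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(gene_id = "character", chrom = "character"))
  if (convention == "1based") df <- annotation_to_zero_based(df)
  gene_annotation(df)
}

#' Coordinate conversions for annotation tables
#'
#' `annotation_to_zero_based()` turns 1-based inclusive (start, end) into
#' 0-based half-open; `annotation_to_one_based()` is its inverse.
#'
#' @param df annotation-style data.frame with `start`, `end` columns.
#' @return data.frame with converted coordinates (tss dropped; recomputed on
#'   validation).
#' @export
annotation_to_zero_based <- function(df) {
  df$start <- df$start - 1L
  df$tss <- NULL
  df
}

#' @rdname annotation_to_zero_based
#' @export
annotation_to_one_based <- function(df) {
  df <- as.data.frame(df)
  df$start <- df$start + 1L
  df$tss <- NULL
  class(df) <- "data.frame"
  df
}

#' @export
write_annotation <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- GenomicInterval collections (BED) -------------------------------------

#' Construct a genomic interval table
#'
#' Plain data.frame carrier for BED records: `chrom`, `start`, `end` (0-based
#' half-open), optional `label`, optional `score`.
#'
#' @param chrom,start,end,label,score vectors of equal length.
#' @return data.frame of class `GenomicIntervals`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_,
                              score = NA_real_) {
  if (any(is.na(chrom) | !nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("interval start >= end (%s:%d-%d)", chrom[i], start[i], end[i]))
  }
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), label = as.character(label),
                       score = as.numeric(score), stringsAsFactors = FALSE),
            class = c("GenomicIntervals", "data.frame"))
}

#' Read a BED3/BED4/BED5 file into a GenomicIntervals table
#'
#' @param path BED path (0-based half-open, tab-separated).
#' @return [genomic_intervals()] table in input order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path, " (< 3 columns)")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  rev <- which(start >= end)
  if (length(rev))
    stop(sprintf("BED line %d: start >= end (%s:%d-%d)", rev[1],
                 chrom[rev[1]], start[rev[1]], end[rev[1]]))
  label <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""), NA_character_)))
  genomic_intervals(chrom, start, end, label, score)
}

#' Write a GenomicIntervals table as BED
#'
#' Emits as many columns as are populated (3, 4 or 5).
#' @param gi GenomicIntervals.
#' @param path output path.
#' @export
write_bed <- function(gi, path) {
  cols <- list(gi$chrom, gi$start, gi$end)
  if (!all(is.na(gi$label)) || !all(is.na(gi$score))) cols <- c(cols, list(gi$label))
  if (!all(is.na(gi$score))) cols <- c(cols, list(gi$score))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# GRanges bridge: internal 0-based half-open -> GRanges 1-based closed
gi_to_gr <- function(gi) {
  GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(gi$start + 1L, gi$end))
}

# point positions (0-based) -> width-1 GRanges
pos_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

# ---- LoopSet (BEDPE) -------------------------------------------------------

#' Construct a chromatin loop set
#'
#' @param df data.frame with chrom1,start1,end1,chrom2,start2,end2 and
#'   optional loop_id (assigned sequentially when absent).
#' @return data.frame of class `LoopSet`.
#' @export
loop_set <- function(df) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing loop columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    if (any(df$start1 >= df$end1) || any(df$start2 >= df$end2))
      stop("loop feet require start < end")
    same <- df$chrom1 == df$chrom2 & df$start1 == df$start2 & df$end1 == df$end2
    if (any(same)) stop("loop with two identical feet at row ", which(same)[1])
  }
  if (is.null(df$loop_id)) df$loop_id <- if (nrow(df)) paste0("loop_", seq_len(nrow(df))) else character()
  class(df) <- c("LoopSet", "data.frame")
  df
}

#' Read chromatin loops from BEDPE
#'
#' @param path BEDPE path (>= 6 columns; column 7, when present, is the loop id).
#' @return [loop_set()] object.
#' @export
read_bedpe_loops <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(loop_set(data.frame(chrom1 = character(), start1 = integer(),
                               end1 = integer(), chrom2 = character(),
                               start2 = integer(), end2 = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("BEDPE line ", which(nf < 6)[1], " has fewer than 6 columns")
  get <- function(k) vapply(fields, `[[`, "", k)
  df <- data.frame(chrom1 = get(1), start1 = as.integer(get(2)), end1 = as.integer(get(3)),
                   chrom2 = get(4), start2 = as.integer(get(5)), end2 = as.integer(get(6)),
                   stringsAsFactors = FALSE)
  if (all(nf >= 7)) df$loop_id <- get(7)
  loop_set(df)
}

#' Write loops as BEDPE
#' @param loops LoopSet.
#' @param path output path.
#' @export
write_bedpe_loops <- function(loops, path) {
  lines <- paste(loops$chrom1, loops$start1, loops$end1,
                 loops$chrom2, loops$start2, loops$end2, loops$loop_id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---- MethylationMatrix -----------------------------------------------------

#' Construct a CpG methylation beta matrix with positions
#'
#' @param beta numeric CpGs x samples matrix, values in \[0, 1\] or NA.
#' @param positions data.frame with `cpg_id`, `chrom`, `pos` (0-based), one
#'   row per CpG in `beta`.
#' @return list of class `MethylationMatrix` with elements `beta`, `positions`.
#' @export
methylation_matrix <- function(beta, positions) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta needs CpG rownames and sample colnames")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  miss <- setdiff(rownames(beta), positions$cpg_id)
  if (length(miss))
    stop("CpGs without a position: ", paste(utils::head(miss, 5), collapse = ", "))
  positions <- positions[match(rownames(beta), positions$cpg_id), , drop = FALSE]
  rownames(positions) <- NULL
  structure(list(beta = beta, positions = positions), class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d CpGs x %d samples (%.1f%% missing)\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(is.na(x$beta))))
  invisible(x)
}

# ---- ATACMatrix ------------------------------------------------------------

#' Construct a normalized ATAC peak signal matrix
#'
#' @param signal numeric peaks x samples matrix of normalized accessibility.
#' @param peaks GenomicIntervals with `label` = peak id, one per signal row.
#' @return list of class `ATACMatrix`.
#' @export
atac_matrix <- function(signal, peaks) {
  if (is.null(rownames(signal))) stop("signal needs peak id rownames")
  if (!all(is.finite(signal))) stop("ATAC signal must be finite")
  miss <- setdiff(rownames(signal), peaks$label)
  if (length(miss))
    stop("peaks without an interval: ", paste(utils::head(miss, 5), collapse = ", "))
  peaks <- peaks[match(rownames(signal), peaks$label), , drop = FALSE]
  structure(list(signal = signal, peaks = peaks), class = "ATACMatrix")
}

# ---- TFBSCollection --------------------------------------------------------

#' Construct a collection of TFBS interval sets
#'
#' @param sets named list of GenomicIntervals, one element per TFBS set
#'   (TF name + experiment); every set must be non-empty.
#' @return list of class `TFBSCollection`.
#' @export
tfbs_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("TFBS sets need unique names")
  empty <- names(sets)[vapply(sets, nrow, 0L) == 0]
  if (length(empty)) stop("empty TFBS set(s): ", paste(empty, collapse = ", "))
  structure(sets, class = "TFBSCollection")
}

# ---- SegmentationTrack -----------------------------------------------------

#' The 13 chromatin-state labels used by the segmentation tracks
#' @export
CHROMHMM_STATES <- c("PrAct", "PrFlk", "EhAct", "EhGen", "TxAct", "TxFlk",
                     "RepPC", "WkREP", "PrBiv", "EhBiv", "RpZNF", "Htchr", "QsLow")

#' Construct a chromatin-state segmentation track
#'
#' @param cell_line label for the source cell line.
#' @param segments GenomicIntervals whose `label` is one of the 13 states;
#'   segments on one chromosome must not overlap.
#' @return list of class `SegmentationTrack`.
#' @export
segmentation_track <- function(cell_line, segments) {
  bad <- setdiff(unique(segments$label), CHROMHMM_STATES)
  if (length(bad)) stop("unknown chromatin state label(s): ", paste(bad, collapse = ", "))
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on ", ch)
  }
  structure(list(cell_line = cell_line, segments = segments),
            class = "SegmentationTrack")
}

# ---- SingleCellDataset -----------------------------------------------------

#' The nine cell-type labels of the single-cell compartment
#' @export
SC_CELL_TYPES <- c("normal_epithelial", "cancer_epithelial", "myeloid", "T",
                   "B", "endothelial", "plasmablast", "CAF", "PVL")

#' Construct a labeled single-cell count dataset
#'
#' @param counts integer genes x cells matrix (may be a sparse `dgCMatrix`).
#' @param cell_type named character vector, one label per cell, drawn from
#'   [SC_CELL_TYPES].
#' @return list of class `SingleCellDataset`.
#' @export
single_cell_dataset <- function(counts, cell_type) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs gene and cell names")
  v <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  miss <- setdiff(colnames(counts), names(cell_type))
  if (length(miss)) stop("unlabeled cells: ", paste(utils::head(miss, 5), collapse = ", "))
  bad <- setdiff(unique(cell_type), SC_CELL_TYPES)
  if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  structure(list(counts = counts, cell_type = cell_type[colnames(counts)]),
            class = "SingleCellDataset")
}

#' Read / write single-cell counts as MatrixMarket plus id files
#'
#' `<prefix>.mtx` stores the counts, `<prefix>.genes.txt` and
#' `<prefix>.cells.txt` the row/column ids, `<prefix>.celltypes.tsv` the labels.
#'
#' @param prefix path prefix.
#' @rdname sc_io
#' @export
read_single_cell <- function(prefix) {
  counts <- as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(counts) <- readLines(paste0(prefix, ".cells.txt"))
  lab <- utils::read.delim(paste0(prefix, ".celltypes.tsv"), sep = "\t")
  single_cell_dataset(counts, stats::setNames(lab$cell_type, lab$cell_id))
}

#' @param sc SingleCellDataset.
#' @rdname sc_io
#' @export
write_single_cell <- function(sc, prefix) {
  Matrix::writeMM(as(as(sc$counts, "dMatrix"), "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(sc$counts), paste0(prefix, ".genes.txt"))
  writeLines(colnames(sc$counts), paste0(prefix, ".cells.txt"))
  utils::write.table(data.frame(cell_id = names(sc$cell_type),
                                cell_type = unname(sc$cell_type)),
                     paste0(prefix, ".celltypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

# ---- generic matrix TSV helpers -------------------------------------------

#' Read / write a generic numeric matrix as TSV (ids in the first column)
#' @param path TSV path.
#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @param m numeric matrix with rownames.
#' @param id_col header name of the id column on write.
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
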