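# Synthetic two-cohort generator with planted ground truth. It emulates the
# statistical structure the analysis assumes: three latent drivers (ESR1
# activity, fibroblast fraction, lymphocyte fraction) inducing three
# lncRNA/mRNA co-expression blocks, ER-dependent differential expression,
# prognostic lncRNAs, enhancer CpGs anti-correlated with their target
# lncRNAs, ER-dependent ATAC accessibility, state-labeled segmentations,
# subtype-biased TFBS placement, chromatin loops joining enhancer CpGs to
# lncRNA TSSs, and cell-type-structured single-cell counts.

#' Simulation configuration
#'
#' Defaults define the reference study conditions: two cohorts of 300
#' samples, 600 lncRNAs (clusters of 120/60/40 plus background), 2000 mRNAs
#' (blocks of 400/200/100), 75% ER+ samples, 50 planted enhancer CpG-lncRNA
#' pairs (half loop-supported) among 5000 decoy CpGs.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_samples samples per cohort.
#' @param n_lnc,n_mrna gene counts.
#' @param er_pos_fraction Bernoulli probability of ER+ per sample.
#' @param lnc_cluster_sizes sizes of lncRNA clusters 1/2/3.
#' @param mrna_cluster_sizes sizes of mRNA blocks A/B/C.
#' @param effect_sizes per-block driver effect on log2 expression (per
#'   standardized latent unit).
#' @param strength_range lncRNA per-gene coupling-strength multiplier range
#'   (uniform): makes connectivity heterogeneous within blocks, as in real
#'   co-expression networks, so the above-average-degree filter separates
#'   strongly from weakly connected genes instead of whole blocks.
#' @param mrna_strength_ranges per-block mRNA coupling-strength ranges;
#'   smaller blocks are given tighter coupling so block degree distributions
#'   overlap despite unequal lncRNA cluster sizes.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param n_de_extra extra background lncRNAs with a direct ER shift.
#' @param de_extra_lfc log2 fold change of those genes (alternating sign).
#' @param enh_er_lfc direct ER log2 fold change given to the enhancer-pair
#'   target lncRNAs (alternating sign, so kept CpGs split into ER+ and ER-
#'   associated groups).
#' @param frac_low_expressed,frac_low_variance background lncRNA fractions
#'   removed by the TPM / IQR filters (generator realism).
#' @param n_chrom,chrom_length genome shape.
#' @param overlap_fraction fraction of lncRNAs placed inside protein-coding
#'   loci (promoter truth: overlapping).
#' @param n_cpg decoy CpG count.
#' @param n_enhancer_pairs planted enhancer CpG-lncRNA pairs.
#' @param looped_fraction fraction of planted pairs joined by a loop.
#' @param n_decoy_loops loops touching neither CpGs nor TSSs.
#' @param meth_slope,meth_noise_sd logistic link strength and noise of the
#'   methylation-expression coupling.
#' @param missing_rate random missingness injected into beta values.
#' @param frac_high_missing fraction of decoy CpGs given > 50% missingness.
#' @param atac_er_effect ER-dependent accessibility shift at subtype-biased
#'   promoters/enhancers.
#' @param atac_noise_sd ATAC signal noise.
#' @param baseline_hazard exponential baseline hazard (per day).
#' @param censor_hazard independent censoring hazard (per day).
#' @param n_prognostic,prognostic_beta planted prognostic lncRNAs and their
#'   log-hazard per sd of expression.
#' @param n_cells_per_type single-cell compartment size per cell type.
#' @param sc_mean_depth mean library size of a cell.
#' @param sc_effect fold elevation of a cluster lncRNA in its home cell types.
#' @param sc_dispersion negative-binomial size parameter.
#' @param sc_dropout extra dropout probability applied to counts.
#' @param batch_shift additive log2 baseline shift of cohort 2.
#' @return validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1,
                       n_samples = 300,
                       n_lnc = 600,
                       n_mrna = 2000,
                       er_pos_fraction = 0.75,
                       lnc_cluster_sizes = c(120, 60, 40),
                       mrna_cluster_sizes = c(300, 250, 200),
                       effect_sizes = c(1, 1, 1),
                       strength_range = c(0.35, 1.6),
                       mrna_strength_ranges = list(A = c(0.30, 0.95),
                                                   B = c(0.50, 1.25),
                                                   C = c(0.90, 1.60)),
                       noise_sd = 1.0,
                       n_de_extra = 30,
                       de_extra_lfc = 1.0,
                       enh_er_lfc = 0.7,
                       frac_low_expressed = 0.05,
                       frac_low_variance = 0.05,
                       n_chrom = 4,
                       chrom_length = 2e7,
                       overlap_fraction = 0.2,
                       n_cpg = 5000,
                       n_enhancer_pairs = 50,
                       looped_fraction = 0.5,
                       n_decoy_loops = 100,
                       meth_slope = 2.0,
                       meth_noise_sd = 0.3,
                       missing_rate = 0.02,
                       frac_high_missing = 0.01,
                       atac_er_effect = 1.0,
                       atac_noise_sd = 0.5,
                       baseline_hazard = 2e-4,
                       censor_hazard = 2e-4,
                       n_prognostic = 5,
                       prognostic_beta = 0.8,
                       n_cells_per_type = 100,
                       sc_mean_depth = 2000,
                       sc_effect = 8,
                       sc_dispersion = 2,
                       sc_dropout = 0,
                       batch_shift = 0.3) {
  cfg <- as.list(environment())
  stopifnot(length(lnc_cluster_sizes) == 3, length(mrna_cluster_sizes) == 3,
            length(effect_sizes) == 3)
  if (n_samples < 1 || n_lnc < 1 || n_mrna < 1 || n_chrom < 1)
    stop("counts must be positive")
  if (er_pos_fraction <= 0 || er_pos_fraction > 1)
    stop("er_pos_fraction must lie in (0, 1]")
  if (sum(lnc_cluster_sizes) > n_lnc) stop("lncRNA cluster sizes exceed n_lnc")
  if (sum(mrna_cluster_sizes) > n_mrna) stop("mRNA cluster sizes exceed n_mrna")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (seed < 0 || seed >= 2^31 - 10000) stop("seed out of range")
  structure(cfg, class = "SimulationConfig")
}

# stage-specific deterministic sub-seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(genome = 101, cohort1 = 211, cohort2 = 223, survival = 307,
            single_cell = 401, atac = 503, meth = 601)
  (as.numeric(seed) * 7919 + offs[[stage]]) %% 2147483647
}

# nominal latent moments used to standardize drivers (fixed constants, so
# samples stay independent)
.latents_nominal <- function(cfg) {
  f <- cfg$er_pos_fraction
  esr1_mean <- 0.6 * f
  esr1_sd <- sqrt(0.6^2 * f * (1 - f) + 0.9^2)
  list(esr1 = c(esr1_mean, esr1_sd),
       fib = c(1 / 3, sqrt(2 * 4 / ((2 + 4)^2 * (2 + 4 + 1)))),
       lym = c(0.3 - 0.1 * f, 0.13))
}

#' Generate the synthetic genome and its structural truth
#'
#' Places lncRNA and protein-coding genes on a slot grid (a configured
#' fraction of lncRNAs inside protein-coding loci), builds chromatin-state
#' segmentation tracks, subtype-biased TFBS sets, ATAC peak intervals, CpG
#' positions (planted enhancer CpGs inside enhancer segments, >= 10 kb from
#' their target TSS on the same chromosome), chromatin loops joining looped
#' enhancer pairs, decoy loops, and the full planted-truth record.
#'
#' @param cfg [sim_config()].
#' @return list of class `SyntheticGenome`: annotation, segmentations (list
#'   of SegmentationTrack), tfbs (TFBSCollection), atac_peaks
#'   (GenomicIntervals), cpg_positions (data.frame), loops (LoopSet),
#'   truth (list).
#' @export
generate_genome <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "genome"))
  n_genes <- cfg$n_lnc + cfg$n_mrna
  genes_per_chrom <- ceiling(n_genes / cfg$n_chrom)
  gene_region <- 0.7 * cfg$chrom_length
  slot_w <- floor(gene_region / genes_per_chrom)
  if (slot_w < 12000)
    stop("chromosome too short for the requested gene count; increase chrom_length")

  gene_ids <- c(sprintf("LNC%04d", seq_len(cfg$n_lnc)),
                sprintf("PCG%04d", seq_len(cfg$n_mrna)))
  biotype <- rep(c("lncRNA", "protein_coding"), c(cfg$n_lnc, cfg$n_mrna))
  # shuffle so every chromosome carries both biotypes
  mix <- order(stats::runif(n_genes))
  gene_ids <- gene_ids[mix]; biotype <- biotype[mix]
  chrom <- paste0("chr", ((seq_len(n_genes) - 1) %/% genes_per_chrom) + 1)
  slot_idx <- (seq_len(n_genes) - 1) %% genes_per_chrom
  slot_start <- slot_idx * slot_w
  glen <- ifelse(biotype == "lncRNA", 2000L, 5000L)
  margin <- 3000L
  start <- as.integer(slot_start + margin)
  end <- as.integer(start + glen)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  # lncRNA truth clusters (assigned on the original id order)
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lnc))
  szl <- cfg$lnc_cluster_sizes
  lnc_cluster <- stats::setNames(rep("none", cfg$n_lnc), lnc_ids)
  if (szl[1] > 0) lnc_cluster[seq_len(szl[1])] <- "1"
  if (szl[2] > 0) lnc_cluster[szl[1] + seq_len(szl[2])] <- "2"
  if (szl[3] > 0) lnc_cluster[szl[1] + szl[2] + seq_len(szl[3])] <- "3"
  mrna_ids <- sprintf("PCG%04d", seq_len(cfg$n_mrna))
  szm <- cfg$mrna_cluster_sizes
  mrna_cluster <- stats::setNames(rep("none", cfg$n_mrna), mrna_ids)
  if (szm[1] > 0) mrna_cluster[seq_len(szm[1])] <- "A"
  if (szm[2] > 0) mrna_cluster[szm[1] + seq_len(szm[2])] <- "B"
  if (szm[3] > 0) mrna_cluster[szm[1] + szm[2] + seq_len(szm[3])] <- "C"

  # a configured fraction of lncRNAs is moved inside a protein-coding locus
  is_lnc <- biotype == "lncRNA"
  n_overlap <- round(cfg$overlap_fraction * cfg$n_lnc)
  promoter_class <- stats::setNames(rep("independent", cfg$n_lnc), lnc_ids)
  if (n_overlap > 0) {
    lnc_pos_all <- which(is_lnc)
    host_cand <- which(!is_lnc)
    ov_idx <- sort(sample(lnc_pos_all, n_overlap))
    for (k in seq_along(ov_idx)) {
      i <- ov_idx[k]
      # host = a protein-coding gene on the same chromosome
      hosts <- host_cand[chrom[host_cand] == chrom[i]]
      h <- hosts[1 + (k - 1) %% length(hosts)]
      start[i] <- start[h] + 1000L
      end[i] <- start[i] + 2001L
      strand[i] <- strand[h]
      promoter_class[gene_ids[i]] <- "overlapping"
    }
  }
  annot <- gene_annotation(data.frame(
    gene_id = gene_ids, chrom = chrom, start = start, end = end,
    strand = strand, biotype = biotype, stringsAsFactors = FALSE))

  tss <- stats::setNames(annot$tss, annot$gene_id)
  gchrom <- stats::setNames(annot$chrom, annot$gene_id)

  # ---- planted enhancer CpG - lncRNA pairs (region B of each chromosome).
  # Targets are background lncRNAs (cluster genes would propagate the CpG
  # signal to every driver-correlated cluster mate on the chromosome); each
  # target receives a direct ER shift so the pairs carry a subtype context.
  enh_region_start <- 0.7 * cfg$chrom_length
  enh_region_end <- 0.9 * cfg$chrom_length
  bg_pool <- names(lnc_cluster)[lnc_cluster == "none"]
  targets <- if (cfg$n_enhancer_pairs == 0) character() else {
    if (length(bg_pool) >= cfg$n_enhancer_pairs) sample(bg_pool, cfg$n_enhancer_pairs)
    else bg_pool[1 + (seq_len(cfg$n_enhancer_pairs) - 1) %% length(bg_pool)]
  }
  enh_er_bias <- rep(c("pos", "neg"), length.out = length(targets))
  # slot width sized for the worst case of every pair landing on one chromosome
  enh_slot_w <- floor((enh_region_end - enh_region_start) /
                        max(1, cfg$n_enhancer_pairs + 1))
  enh_count <- stats::setNames(rep(0L, cfg$n_chrom), paste0("chr", seq_len(cfg$n_chrom)))
  reg_pairs <- NULL
  enh_segments <- NULL
  if (length(targets) > 0) {
    looped <- seq_along(targets) <= round(cfg$looped_fraction * length(targets))
    cpg_chrom <- gchrom[targets]
    cpg_pos <- integer(length(targets))
    state <- character(length(targets))
    for (k in seq_along(targets)) {
      ch <- cpg_chrom[k]
      enh_count[ch] <- enh_count[ch] + 1L
      seg_start <- as.integer(enh_region_start + (enh_count[ch] - 1L) * enh_slot_w + 2000L)
      cpg_pos[k] <- seg_start + 500L
      state[k] <- if (k %% 2 == 0) "EhGen" else "EhAct"
    }
    reg_pairs <- data.frame(
      cpg_id = sprintf("ENHCPG%03d", seq_along(targets)),
      lnc_id = targets, looped = looped, er_bias = enh_er_bias,
      chrom = unname(cpg_chrom), pos = cpg_pos, state = state,
      stringsAsFactors = FALSE)
    enh_segments <- genomic_intervals(reg_pairs$chrom, reg_pairs$pos - 500L,
                                      reg_pairs$pos + 500L, reg_pairs$state)
  }

  # ---- decoy CpGs: uniform over regions A+B (never the decoy-loop region C)
  decoy_chrom <- paste0("chr", sample.int(cfg$n_chrom, cfg$n_cpg, replace = TRUE))
  decoy_pos <- as.integer(floor(stats::runif(cfg$n_cpg, 0, enh_region_end - 1)))
  cpg_positions <- data.frame(
    cpg_id = c(if (!is.null(reg_pairs)) reg_pairs$cpg_id,
               sprintf("CPG%05d", seq_len(cfg$n_cpg))),
    chrom = c(if (!is.null(reg_pairs)) reg_pairs$chrom, decoy_chrom),
    pos = c(if (!is.null(reg_pairs)) reg_pairs$pos, decoy_pos),
    stringsAsFactors = FALSE)

  # ---- segmentation tracks: promoter states (subtype-specific lncRNA
  # promoters are active in their matching cell line and poised/bivalent in
  # the other), TxAct bodies, planted enhancers, assorted decoy states in
  # region C, QsLow fill
  make_track <- function(cell_line) {
    plabel <- rep("PrAct", nrow(annot))
    cl_of_gene <- lnc_cluster[annot$gene_id]  # NA for mRNAs
    if (cell_line == "lumA_line") {
      plabel[!is.na(cl_of_gene) & cl_of_gene == "3"] <- "PrBiv"
    } else {
      plabel[!is.na(cl_of_gene) & cl_of_gene == "1"] <- "PrBiv"
    }
    cand <- list()
    if (!is.null(enh_segments)) cand[[length(cand) + 1]] <- enh_segments
    cand[[length(cand) + 1]] <- genomic_intervals(
      annot$chrom, pmax(annot$tss - 500L, 0L), annot$tss + 500L, plabel)
    cand[[length(cand) + 1]] <- genomic_intervals(
      annot$chrom, annot$start, annot$end, "TxAct")
    other <- setdiff(CHROMHMM_STATES, c("EhAct", "EhGen", "PrAct", "QsLow"))
    dec_start <- as.integer(0.92 * cfg$chrom_length +
                              (seq_along(other) - 1) * 20000L)
    for (ch in seq_len(cfg$n_chrom)) {
      cand[[length(cand) + 1]] <- genomic_intervals(
        rep(paste0("chr", ch), length(other)), dec_start, dec_start + 5000L, other)
    }
    all <- do.call(rbind, cand)
    # greedy interval scheduling per chromosome: earlier candidates win
    keep <- logical(nrow(all))
    for (ch in unique(all$chrom)) {
      idx <- which(all$chrom == ch)
      taken_s <- integer(0); taken_e <- integer(0)
      for (i in idx) {
        if (!any(all$start[i] < taken_e & taken_s < all$end[i])) {
          keep[i] <- TRUE
          taken_s <- c(taken_s, all$start[i]); taken_e <- c(taken_e, all$end[i])
        }
      }
    }
    segs <- all[keep, , drop = FALSE]
    # QsLow fill over the gaps
    fill <- list()
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      gaps_s <- c(0L, s$end)
      gaps_e <- c(s$start, as.integer(cfg$chrom_length))
      ok <- gaps_s < gaps_e
      if (any(ok))
        fill[[ch]] <- genomic_intervals(rep(ch, sum(ok)), gaps_s[ok], gaps_e[ok], "QsLow")
    }
    segs <- rbind(segs, do.call(rbind, fill))
    segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
    rownames(segs) <- NULL
    segmentation_track(cell_line, segs)
  }
  segmentations <- list(make_track("lumA_line"), make_track("basal_line"))

  # ---- TFBS sets: ER+-biased in cluster-1 promoters, ER--biased in
  # cluster-3, unbiased decoys everywhere at low rate
  prom_center <- tss[lnc_ids]
  site_at <- function(ids) genomic_intervals(
    gchrom[ids], pmax(prom_center[ids] - 50L, 0L), prom_center[ids] + 50L, ids)
  cl1 <- names(lnc_cluster)[lnc_cluster == "1"]
  cl3 <- names(lnc_cluster)[lnc_cluster == "3"]
  tfbs_sets <- list()
  tfbs_bias <- character()
  mk_set <- function(pool, rate, extra_bg = 5) {
    n_hit <- max(2, round(rate * length(pool)))
    hit <- sample(pool, min(n_hit, length(pool)))
    bg <- sample(lnc_ids, extra_bg)
    site_at(unique(c(hit, bg)))
  }
  if (length(cl1) >= 2) {
    for (k in 1:4) {
      nm <- sprintf("ESR1_exp%d", k)
      tfbs_sets[[nm]] <- mk_set(cl1, 0.6)
      tfbs_bias[nm] <- "ERpos"
    }
  }
  if (length(cl3) >= 2) {
    for (k in 1:4) {
      nm <- sprintf("STAT1_exp%d", k)
      tfbs_sets[[nm]] <- mk_set(cl3, 0.6)
      tfbs_bias[nm] <- "ERneg"
    }
  }
  for (k in 1:4) {
    nm <- sprintf("CTCF_exp%d", k)
    tfbs_sets[[nm]] <- site_at(sample(lnc_ids, max(2, round(0.1 * cfg$n_lnc))))
    tfbs_bias[nm] <- "none"
  }
  tfbs <- tfbs_collection(tfbs_sets)

  # ---- ATAC peaks: promoter peaks for every lncRNA, enhancer peaks at
  # planted CpGs, a few decoys in region B
  peak_list <- list(genomic_intervals(
    gchrom[lnc_ids], pmax(prom_center[lnc_ids] - 300L, 0L),
    prom_center[lnc_ids] + 300L, paste0("peak_prom_", lnc_ids)))
  if (!is.null(reg_pairs))
    peak_list[[2]] <- genomic_intervals(
      reg_pairs$chrom, reg_pairs$pos - 300L, reg_pairs$pos + 300L,
      paste0("peak_enh_", reg_pairs$cpg_id))
  atac_peaks <- do.call(rbind, peak_list)
  rownames(atac_peaks) <- NULL

  # ---- loops: one per looped planted pair + decoys confined to region C
  loop_rows <- list()
  if (!is.null(reg_pairs) && any(reg_pairs$looped)) {
    lp <- reg_pairs[reg_pairs$looped, , drop = FALSE]
    t2 <- tss[lp$lnc_id]
    loop_rows[[1]] <- data.frame(
      chrom1 = lp$chrom, start1 = lp$pos - 500L, end1 = lp$pos + 500L,
      chrom2 = unname(gchrom[lp$lnc_id]), start2 = as.integer(t2 - 500L),
      end2 = as.integer(t2 + 500L),
      loop_id = paste0("planted_", lp$cpg_id), stringsAsFactors = FALSE)
  }
  if (cfg$n_decoy_loops > 0) {
    dch <- paste0("chr", sample.int(cfg$n_chrom, cfg$n_decoy_loops, replace = TRUE))
    base <- as.integer(floor(stats::runif(cfg$n_decoy_loops,
                                          0.90 * cfg$chrom_length + 120000,
                                          0.99 * cfg$chrom_length - 20000)))
    loop_rows[[length(loop_rows) + 1]] <- data.frame(
      chrom1 = dch, start1 = base, end1 = base + 1000L,
      chrom2 = dch, start2 = base + 5000L, end2 = base + 6000L,
      loop_id = sprintf("decoy_loop_%03d", seq_len(cfg$n_decoy_loops)),
      stringsAsFactors = FALSE)
  }
  loops <- loop_set(if (length(loop_rows)) do.call(rbind, loop_rows) else
    data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
               chrom2 = character(), start2 = integer(), end2 = integer()))

  # ---- expression-side truth drawn here so both cohorts share it
  base_expr <- stats::setNames(stats::runif(n_genes, 3, 6), c(lnc_ids, mrna_ids))
  bg_lnc <- setdiff(names(lnc_cluster)[lnc_cluster == "none"], targets)
  n_lowe <- round(cfg$frac_low_expressed * length(bg_lnc))
  low_expressed <- if (n_lowe > 0) sample(bg_lnc, n_lowe) else character()
  rest <- setdiff(bg_lnc, low_expressed)
  n_lowv <- round(cfg$frac_low_variance * length(bg_lnc))
  low_variance <- if (n_lowv > 0) sample(rest, min(n_lowv, length(rest))) else character()
  rest <- setdiff(rest, low_variance)
  de_extra <- if (cfg$n_de_extra > 0 && length(rest) >= cfg$n_de_extra)
    sample(rest, cfg$n_de_extra) else character()
  rest <- setdiff(rest, de_extra)
  prognostic_genes <- if (cfg$n_prognostic > 0 && length(rest) >= cfg$n_prognostic)
    sample(rest, cfg$n_prognostic) else character()
  base_expr[low_expressed] <- 0.1

  # per-gene coupling strength: heterogeneous connectivity within blocks
  strength <- stats::setNames(rep(1, n_genes), c(lnc_ids, mrna_ids))
  lnc_in_block <- names(lnc_cluster)[lnc_cluster != "none"]
  strength[lnc_in_block] <- stats::runif(length(lnc_in_block),
                                         cfg$strength_range[1], cfg$strength_range[2])
  # mRNA coupling-strength profiles per block: smaller blocks are more
  # tightly coupled (mostly hubs), so degree distributions overlap across
  # blocks instead of scaling with the lncRNA cluster sizes
  for (b in c("A", "B", "C")) {
    ids <- names(mrna_cluster)[mrna_cluster == b]
    rng <- cfg$mrna_strength_ranges[[b]]
    strength[ids] <- stats::runif(length(ids), rng[1], rng[2])
  }
  # the designated ESR1 gene tracks its driver tightly (it is the receptor)
  if (szm[1] > 0) strength[mrna_ids[1]] <- 1.5

  # driver coupling per gene: cluster/block genes couple to their block's
  # driver; the remaining background genes (minus the reserved special
  # pools) couple WEAKLY to a random driver. This reproduces the
  # hub-vs-periphery degree structure of real co-expression networks: many
  # low-degree nodes keep the mean degree well below the hub degrees.
  coupling <- stats::setNames(rep("none", n_genes), c(lnc_ids, mrna_ids))
  coupling[names(lnc_cluster)[lnc_cluster != "none"]] <-
    lnc_cluster[lnc_cluster != "none"]
  coupling[names(mrna_cluster)[mrna_cluster != "none"]] <-
    c(A = "1", B = "2", C = "3")[mrna_cluster[mrna_cluster != "none"]]
  have_blocks <- any(cfg$lnc_cluster_sizes > 0)
  periph_lnc <- if (have_blocks) setdiff(rest, prognostic_genes) else character()
  periph_mrna <- if (have_blocks) names(mrna_cluster)[mrna_cluster == "none"] else character()
  periph <- c(periph_lnc, periph_mrna)
  if (length(periph)) {
    coupling[periph] <- as.character(sample.int(3, length(periph), replace = TRUE))
    strength[periph_lnc] <- stats::runif(length(periph_lnc), 0.20, 0.35)
    # periphery mRNAs couple a bit more strongly so they enter the edge set
    # (many low-degree nodes keep the mean mRNA degree below the hub degrees)
    strength[periph_mrna] <- stats::runif(length(periph_mrna), 0.25, 0.40)
  }

  nom <- .latents_nominal(cfg)
  er_gap_esr1 <- 0.6 / nom$esr1[2]
  er_gap_lym <- -0.1 / nom$lym[2]
  # driver-induced ER log2 fold changes (drivers 1 and 3 are ER-linked)
  lnc_coupling <- coupling[lnc_ids]
  lnc_eff <- cfg$effect_sizes[pmax(1, as.integer(
    ifelse(lnc_coupling == "none", "1", lnc_coupling)))] * strength[lnc_ids]
  de_truth <- stats::setNames(rep(0, cfg$n_lnc), lnc_ids)
  de_truth[lnc_coupling == "1"] <- (lnc_eff * er_gap_esr1)[lnc_coupling == "1"]
  de_truth[lnc_coupling == "3"] <- (lnc_eff * er_gap_lym)[lnc_coupling == "3"]
  if (length(de_extra))
    de_truth[de_extra] <- cfg$de_extra_lfc * rep(c(1, -1), length.out = length(de_extra))
  if (length(targets))
    de_truth[targets] <- ifelse(enh_er_bias == "pos", 1, -1) * cfg$enh_er_lfc
  prognostic <- stats::setNames(rep(0, cfg$n_lnc), lnc_ids)
  prognostic[prognostic_genes] <- cfg$prognostic_beta

  truth <- list(
    lnc_cluster = lnc_cluster, mrna_cluster = mrna_cluster,
    driver = c(`1` = "ESR1", `2` = "fibroblast", `3` = "lymphocyte"),
    de_truth = de_truth, prognostic = prognostic,
    reg_pairs = if (is.null(reg_pairs))
      data.frame(cpg_id = character(), lnc_id = character(), looped = logical(),
                 er_bias = character())
    else reg_pairs[, c("cpg_id", "lnc_id", "looped", "er_bias")],
    promoter_class = promoter_class, tfbs_bias = tfbs_bias,
    low_expressed = low_expressed, low_variance = low_variance,
    base_expr = base_expr, strength = strength, coupling = coupling,
    esr1_gene = mrna_ids[1])
  # the designated ESR1 gene must sit in block A so it tracks the ER driver
  if (szm[1] == 0) truth$esr1_gene <- NA_character_

  structure(list(annotation = annot, segmentations = segmentations,
                 tfbs = tfbs, atac_peaks = atac_peaks,
                 cpg_positions = cpg_positions, loops = loops,
                 reg_pair_geometry = reg_pairs, truth = truth, config = cfg),
            class = "SyntheticGenome")
}

#' Generate one bulk cohort from a synthetic genome
#'
#' Draws per-sample latent drivers (ER status, ESR1 activity, fibroblast and
#' lymphocyte fractions; the lymphocyte mean is higher in ER- samples), then
#' log2 expression = baseline (+ batch shift for cohort 2) + block effect x
#' standardized driver + Gaussian noise, inverted to TPM. Enhancer-CpG beta
#' values follow a logistic link on the target lncRNA's standardized log2
#' expression (negative coupling); decoy CpGs are independent Beta draws.
#' ATAC signal at subtype-biased promoters/enhancers shifts with ER status.
#'
#' @param genome [generate_genome()] result.
#' @param cohort_index 1 or 2 (cohort 2 receives the batch shift).
#' @return list of class `SyntheticCohort`: expr (ExpressionMatrix, TPM,
#'   lncRNAs and mRNAs), clinical (ClinicalTable, survival columns NA until
#'   [generate_survival()]), scores_truth (per-sample latents), atac
#'   (ATACMatrix), meth (MethylationMatrix).
#' @export
generate_cohort <- function(genome, cohort_index = 1) {
  if (!inherits(genome, "SyntheticGenome"))
    stop("generate the genome first (generate_genome)")
  if (!cohort_index %in% c(1, 2)) stop("cohort_index must be 1 or 2")
  cfg <- genome$config
  set.seed(stage_seed(cfg$seed, paste0("cohort", cohort_index)))
  n <- cfg$n_samples
  sample_ids <- sprintf("C%d_S%03d", cohort_index, seq_len(n))
  truth <- genome$truth
  nom <- .latents_nominal(cfg)

  er_ind <- stats::rbinom(n, 1, cfg$er_pos_fraction)
  esr1_act <- 0.6 * er_ind + stats::rnorm(n, 0, 0.9)
  fib <- stats::rbeta(n, 2, 4)
  lym <- ifelse(er_ind == 1, stats::rbeta(n, 2, 8), stats::rbeta(n, 3, 7))
  z_esr1 <- (esr1_act - nom$esr1[1]) / nom$esr1[2]
  z_fib <- (fib - nom$fib[1]) / nom$fib[2]
  z_lym <- (lym - nom$lym[1]) / nom$lym[2]
  driver_z <- rbind(`1` = z_esr1, `2` = z_fib, `3` = z_lym)

  annot <- genome$annotation
  gene_ids <- c(names(truth$lnc_cluster), names(truth$mrna_cluster))
  base <- truth$base_expr[gene_ids]
  if (cohort_index == 2) base <- base + cfg$batch_shift
  cl <- truth$coupling[gene_ids]
  eff <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  for (k in 1:3) eff[cl == as.character(k)] <- cfg$effect_sizes[k]
  eff <- eff * truth$strength[gene_ids]

  logx <- matrix(base, nrow = length(gene_ids), ncol = n,
                 dimnames = list(gene_ids, sample_ids))
  signal <- matrix(0, length(gene_ids), n)
  for (k in 1:3) {
    sel <- cl == as.character(k)
    if (any(sel)) signal[sel, ] <- eff[sel] %o% driver_z[as.character(k), ]
  }
  # direct ER shifts for the extra planted DE genes (centered on the ER mix)
  extra <- names(truth$de_truth)[truth$de_truth != 0 &
                                   truth$lnc_cluster[names(truth$de_truth)] == "none"]
  if (length(extra)) {
    shift <- truth$de_truth[extra]
    signal[match(extra, gene_ids), ] <- signal[match(extra, gene_ids), ] +
      shift %o% (er_ind - cfg$er_pos_fraction)
  }
  noise_sd <- rep(cfg$noise_sd, length(gene_ids))
  noise_sd[match(truth$low_variance, gene_ids)] <- 0.02
  logx <- logx + signal +
    matrix(stats::rnorm(length(gene_ids) * n), length(gene_ids), n) * noise_sd
  logx <- pmax(logx, 0)
  logx[match(truth$low_expressed, gene_ids), ] <-
    pmin(logx[match(truth$low_expressed, gene_ids), , drop = FALSE], 0.9)
  expr <- expression_matrix(2^logx - 1, unit = "TPM")

  clinical <- clinical_table(data.frame(
    sample_id = sample_ids,
    er_status = ifelse(er_ind == 1, "pos", "neg"),
    her2_status = sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.15, 0.85)),
    pam50 = ifelse(er_ind == 1,
                   sample(c("LumA", "LumB"), n, replace = TRUE, prob = c(0.7, 0.3)),
                   sample(c("Basal", "Her2", "Normal"), n, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1))),
    os_time = NA_real_, os_event = NA_real_, stringsAsFactors = FALSE))

  # ---- methylation
  geom <- genome$reg_pair_geometry
  n_planted <- if (is.null(geom)) 0L else nrow(geom)
  beta_rows <- list()
  if (n_planted > 0) {
    zx <- t(scale(t(logx[geom$lnc_id, , drop = FALSE])))
    lin <- -cfg$meth_slope * zx +
      matrix(stats::rnorm(n_planted * n, 0, cfg$meth_noise_sd), n_planted, n)
    beta_rows$planted <- stats::plogis(lin)
    rownames(beta_rows$planted) <- geom$cpg_id
  }
  decoy_ids <- setdiff(genome$cpg_positions$cpg_id,
                       if (n_planted) geom$cpg_id else character())
  bd <- matrix(stats::rbeta(length(decoy_ids) * n, 2, 2), length(decoy_ids), n,
               dimnames = list(decoy_ids, sample_ids))
  beta_rows$decoy <- bd
  beta <- do.call(rbind, beta_rows)
  colnames(beta) <- sample_ids
  # random missingness plus a few heavily missing decoys
  nmiss <- round(cfg$missing_rate * length(beta))
  if (nmiss > 0) beta[sample.int(length(beta), nmiss)] <- NA
  n_high <- round(cfg$frac_high_missing * length(decoy_ids))
  if (n_high > 0) {
    hm <- sample(decoy_ids, n_high)
    for (cg in hm) beta[cg, sample.int(n, ceiling(0.6 * n))] <- NA
  }
  meth <- methylation_matrix(beta, genome$cpg_positions)

  # ---- ATAC: base signal + ER-dependent shift at subtype-biased peaks
  peaks <- genome$atac_peaks
  n_peaks <- nrow(peaks)
  atac_sig <- matrix(stats::rnorm(n_peaks * n, 2, cfg$atac_noise_sd), n_peaks, n,
                     dimnames = list(peaks$label, sample_ids))
  lnc_of_peak <- sub("^peak_prom_", "", peaks$label)
  enh_of_peak <- sub("^peak_enh_", "", peaks$label)
  cl_of_peak <- rep("none", n_peaks)
  prom_mask <- startsWith(peaks$label, "peak_prom_")
  cl_of_peak[prom_mask] <- truth$lnc_cluster[lnc_of_peak[prom_mask]]
  enh_mask <- startsWith(peaks$label, "peak_enh_")
  if (any(enh_mask) && n_planted > 0) {
    bias <- geom$er_bias[match(enh_of_peak[enh_mask], geom$cpg_id)]
    cl_of_peak[enh_mask] <- c(pos = "1", neg = "3")[bias]
  }
  atac_sig[cl_of_peak == "1", ] <- atac_sig[cl_of_peak == "1", , drop = FALSE] +
    rep(cfg$atac_er_effect * er_ind, each = sum(cl_of_peak == "1"))
  atac_sig[cl_of_peak == "3", ] <- atac_sig[cl_of_peak == "3", , drop = FALSE] +
    rep(cfg$atac_er_effect * (1 - er_ind), each = sum(cl_of_peak == "3"))
  atac <- atac_matrix(atac_sig, peaks)

  scores_truth <- data.frame(sample_id = sample_ids, er = er_ind,
                             esr1_activity = esr1_act, fib_frac = fib,
                             lym_frac = lym, stringsAsFactors = FALSE)
  structure(list(expr = expr, clinical = clinical, scores_truth = scores_truth,
                 atac = atac, meth = meth, cohort_index = cohort_index),
            class = "SyntheticCohort")
}

#' Plant survival outcomes on a cohort
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(planted log-hazard x standardized log2
#' expression))`; censoring is an independent exponential clock.
#'
#' @param cohort SyntheticCohort (expression present).
#' @param genome SyntheticGenome carrying the prognostic truth.
#' @param baseline_hazard,censor_hazard override the config values.
#' @return the cohort with os_time / os_event filled in.
#' @export
generate_survival <- function(cohort, genome, baseline_hazard = NULL,
                              censor_hazard = NULL) {
  cfg <- genome$config
  h0 <- if (is.null(baseline_hazard)) cfg$baseline_hazard else baseline_hazard
  hc <- if (is.null(censor_hazard)) cfg$censor_hazard else censor_hazard
  if (h0 <= 0) stop("baseline hazard must be positive")
  set.seed(stage_seed(cfg$seed, "survival") + cohort$cohort_index)
  prog <- genome$truth$prognostic
  genes <- names(prog)[prog != 0]
  n <- ncol(cohort$expr)
  lp <- rep(0, n)
  if (length(genes)) {
    lx <- log2(unclass(cohort$expr)[genes, , drop = FALSE] + 1)
    zx <- t(scale(t(lx)))
    lp <- colSums(zx * prog[genes])
  }
  t_event <- stats::rexp(n, rate = h0 * exp(lp))
  t_cens <- stats::rexp(n, rate = hc)
  cohort$clinical$os_time <- pmin(t_event, t_cens)
  cohort$clinical$os_event <- as.numeric(t_event <= t_cens)
  cohort$clinical <- clinical_table(as.data.frame(cohort$clinical))
  cohort
}

#' Generate the cell-type-structured single-cell dataset
#'
#' Counts are negative binomial with cell-type-specific means: cluster-1
#' lncRNAs are elevated in cancer epithelial cells, cluster-2 in CAF/PVL,
#' cluster-3 in T/B/myeloid cells; library sizes are log-normal.
#'
#' @param genome SyntheticGenome.
#' @param n_cells_per_type override the config value.
#' @return [single_cell_dataset()] over all lncRNAs plus the block mRNAs.
#' @export
generate_single_cell <- function(genome, n_cells_per_type = NULL) {
  cfg <- genome$config
  if (is.null(n_cells_per_type)) n_cells_per_type <- cfg$n_cells_per_type
  if (n_cells_per_type < 1) stop("need >= 1 cell per type")
  set.seed(stage_seed(cfg$seed, "single_cell"))
  truth <- genome$truth
  genes <- c(names(truth$lnc_cluster),
             names(truth$mrna_cluster)[truth$mrna_cluster != "none"])
  cl <- c(truth$lnc_cluster,
          c(A = "1", B = "2", C = "3")[truth$mrna_cluster[truth$mrna_cluster != "none"]])
  names(cl) <- genes
  types <- SC_CELL_TYPES
  cell_type <- rep(types, each = n_cells_per_type)
  n_cells <- length(cell_type)
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  names(cell_type) <- cell_ids
  home <- list(`1` = c("cancer_epithelial"),
               `2` = c("CAF", "PVL"),
               `3` = c("T", "B", "myeloid"))
  base_mu <- exp(stats::rnorm(length(genes), log(0.2), 0.5))
  mu <- matrix(base_mu, length(genes), n_cells, dimnames = list(genes, cell_ids))
  for (k in names(home)) {
    gs <- cl == k
    cs <- cell_type %in% home[[k]]
    if (any(gs) && any(cs)) mu[gs, cs] <- mu[gs, cs] * cfg$sc_effect
  }
  depth <- stats::rlnorm(n_cells, log(cfg$sc_mean_depth), 0.3)
  mu <- sweep(mu, 2L, depth / mean(colSums(mu)), "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$sc_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  if (cfg$sc_dropout > 0)
    counts[stats::runif(length(counts)) < cfg$sc_dropout] <- 0L
  single_cell_dataset(Matrix::Matrix(counts, sparse = TRUE), cell_type)
}

#' Brute-force audit of the planted structural truth
#'
#' Verifies, by exhaustive scans of the emitted objects, that every planted
#' looped pair has its CpG in one loop foot and its target TSS in the other,
#' that every planted CpG lies inside an enhancer-labeled segment >= 10 kb
#' from the target TSS on the same chromosome, and that the driver map is
#' the fixed bijection.
#'
#' @param genome SyntheticGenome.
#' @return invisible TRUE; stops with a message on any violation.
#' @export
audit_truth <- function(genome) {
  truth <- genome$truth
  geom <- genome$reg_pair_geometry
  if (!identical(unname(truth$driver[c("1", "2", "3")]),
                 c("ESR1", "fibroblast", "lymphocyte")))
    stop("driver map is not the expected bijection")
  if (!is.null(geom) && nrow(geom) > 0) {
    annot <- genome$annotation
    segs <- genome$segmentations[[1]]$segments
    enh <- segs[segs$label %in% c("EhAct", "EhGen"), , drop = FALSE]
    for (i in seq_len(nrow(geom))) {
      tss <- annot$tss[annot$gene_id == geom$lnc_id[i]]
      tch <- annot$chrom[annot$gene_id == geom$lnc_id[i]]
      if (tch != geom$chrom[i]) stop("planted pair not cis: ", geom$cpg_id[i])
      if (abs(geom$pos[i] - tss) < 10000)
        stop("planted CpG too close to target TSS: ", geom$cpg_id[i])
      inside <- any(enh$chrom == geom$chrom[i] & enh$start <= geom$pos[i] &
                      geom$pos[i] < enh$end)
      if (!inside) stop("planted CpG outside enhancer segments: ", geom$cpg_id[i])
      loops <- genome$loops
      in1 <- loops$chrom1 == geom$chrom[i] & loops$start1 <= geom$pos[i] &
        geom$pos[i] < loops$end1
      in2 <- loops$chrom2 == tch & loops$start2 <= tss & tss < loops$end2
      has_loop <- any(in1 & in2)
      if (geom$looped[i] && !has_loop)
        stop("looped pair without a joining loop: ", geom$cpg_id[i])
      if (!geom$looped[i] && has_loop)
        stop("unlooped pair with a joining loop: ", geom$cpg_id[i])
    }
  }
  invisible(TRUE)
}
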