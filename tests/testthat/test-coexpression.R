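mk_expr <- function(m) expression_matrix(m, "log2p1")

test_that("Spearman pair matrix matches average-rank oracles", {
  set.seed(31)
  n <- 12
  x <- abs(matrix(stats::rnorm(2 * n, 5), 2, n,
                  dimnames = list(c("l1", "l2"), paste0("s", 1:n))))
  x["l2", ] <- 10 - x["l1", ]  # exact anti-correlation
  y <- x; rownames(y) <- c("m1", "m2")
  y["m1", ] <- x["l1", ]
  res <- spearman_pair_matrix(mk_expr(x), mk_expr(y))
  expect_equal(res$rho["l1", "m1"], 1)
  expect_equal(res$rho["l2", "m1"], -1)

  # tied vectors against the explicit rank computation
  a <- matrix(rep(c(1, 2, 2, 4, 5, 1, 3, 2, 2, 4), 1), 1, 10,
              dimnames = list("lnc", paste0("s", 1:10)))
  b <- matrix(c(3, 1, 1, 2, 5, 2, 2, 4, 1, 3), 1, 10,
              dimnames = list("mrna", paste0("s", 1:10)))
  res <- spearman_pair_matrix(mk_expr(a), mk_expr(b))
  expect_equal(res$rho[1, 1], oracle_spearman(a[1, ], b[1, ]), tolerance = 1e-12)

  # constant genes produce NA with a warning and leave the test count
  cc <- rbind(a, const = rep(2, 10))
  expect_warning(res <- spearman_pair_matrix(mk_expr(cc), mk_expr(b)),
                 "constant")
  expect_true(is.na(res$rho["const", 1]))
})

test_that("Bonferroni replication applies strict thresholds in both cohorts", {
  mk_cor <- function(rho, p) list(rho = rho, p = p, n_samples = 50)
  dn <- list(c("l1", "l2"), c("m1", "m2"))
  rho <- matrix(0.5, 2, 2, dimnames = dn)
  # boundary: p * n_tests == alpha exactly -> not kept (strict <)
  p_edge <- matrix(0.05 / 4, 2, 2, dimnames = dn)
  res <- bonferroni_replicated_edges(mk_cor(rho, p_edge), mk_cor(rho, p_edge))
  expect_equal(nrow(res$edges), 0L)
  # just under the boundary -> kept
  p_in <- matrix(0.05 / 4 - 1e-12, 2, 2, dimnames = dn)
  res <- bonferroni_replicated_edges(mk_cor(rho, p_in), mk_cor(rho, p_in))
  expect_equal(nrow(res$edges), 4L)
  # sign conflicts are dropped and counted
  res <- bonferroni_replicated_edges(mk_cor(rho, p_in), mk_cor(-rho, p_in))
  expect_equal(nrow(res$edges), 0L)
  expect_equal(res$n_sign_conflict, 4L)
  expect_error(bonferroni_replicated_edges(mk_cor(rho, p_in),
                                           mk_cor(rho, p_in), alpha = 1.5),
               "alpha")

  # toy grid against an exhaustive double loop
  set.seed(33)
  dn5 <- list(paste0("l", 1:5), paste0("m", 1:5))
  rhoA <- matrix(stats::runif(25, -1, 1), 5, 5, dimnames = dn5)
  rhoB <- matrix(stats::runif(25, -1, 1), 5, 5, dimnames = dn5)
  pA <- matrix(stats::runif(25, 1e-4, 0.2), 5, 5, dimnames = dn5) / 100
  pB <- matrix(stats::runif(25, 1e-4, 0.2), 5, 5, dimnames = dn5) / 100
  res <- bonferroni_replicated_edges(mk_cor(rhoA, pA), mk_cor(rhoB, pB))
  manual <- 0
  for (i in 1:5) for (j in 1:5) {
    if (pA[i, j] * 25 < 0.05 && pB[i, j] * 25 < 0.05 &&
        sign(rhoA[i, j]) == sign(rhoB[i, j])) manual <- manual + 1
  }
  expect_equal(nrow(res$edges), manual)
})

test_that("degree filtering retains above-average genes then strong edges", {
  edges <- data.frame(
    lnc_id = c(rep("lA", 10), rep("lB", 2)),
    mrna_id = paste0("m", c(1:10, 1:2)),
    rho_A = 0.6, p_A = 1e-9, rho_B = 0.6, p_B = 1e-9, sign = "+")
  es <- structure(list(edges = edges), class = "CorrelationEdgeSet")
  res <- degree_and_rho_filter(es)
  expect_equal(res$lnc_retained, "lA")  # degree 10 vs mean 6

  # the rho threshold must hold in both cohorts
  edges2 <- edges
  edges2$rho_B[1] <- 0.35
  res2 <- degree_and_rho_filter(structure(list(edges = edges2),
                                          class = "CorrelationEdgeSet"))
  expect_false("m1" %in% res2$edges$mrna_id[res2$edges$lnc_id == "lA"])

  # random fixture vs an independently coded filter
  set.seed(35)
  big <- data.frame(
    lnc_id = sample(paste0("l", 1:50), 600, replace = TRUE),
    mrna_id = sample(paste0("m", 1:200), 600, replace = TRUE),
    rho_A = stats::runif(600, -0.9, 0.9), p_A = 1e-9,
    rho_B = stats::runif(600, -0.9, 0.9), p_B = 1e-9, sign = "+")
  big <- big[!duplicated(big[, 1:2]), ]
  res3 <- degree_and_rho_filter(structure(list(edges = big),
                                          class = "CorrelationEdgeSet"),
                                rho_min = 0.4)
  dl <- table(big$lnc_id); dm <- table(big$mrna_id)
  keepl <- names(dl)[dl > mean(dl)]; keepm <- names(dm)[dm > mean(dm)]
  sel <- big$lnc_id %in% keepl & big$mrna_id %in% keepm &
    abs(big$rho_A) > 0.4 & abs(big$rho_B) > 0.4
  expect_equal(res3$edges, big[sel, ])
  expect_setequal(res3$lnc_retained, keepl)
})

test_that("binarized biclustering recovers planted blocks and is label-invariant", {
  mk_edges <- function(lncs, mrnas, sign = "+") {
    expand <- expand.grid(lnc_id = lncs, mrna_id = mrnas,
                          stringsAsFactors = FALSE)
    expand$rho_A <- ifelse(sign == "+", 0.8, -0.8)
    expand$p_A <- 1e-12; expand$rho_B <- expand$rho_A; expand$p_B <- 1e-12
    expand$sign <- sign
    expand
  }
  edges <- rbind(mk_edges(paste0("x", 1:6), paste0("ma", 1:7)),
                 mk_edges(paste0("y", 1:5), paste0("mb", 1:6), "-"),
                 mk_edges(paste0("z", 1:4), paste0("mc", 1:5)))
  filt <- list(edges = edges)
  bic <- binarize_bicluster(filt, 3, 3)
  # exact recovery of the planted 3x3 partition; labels ordered by size
  expect_equal(unname(bic$lnc_labels[paste0("x", 1:6)]), rep(1L, 6))
  expect_equal(unname(bic$lnc_labels[paste0("y", 1:5)]), rep(2L, 5))
  expect_equal(unname(bic$lnc_labels[paste0("z", 1:4)]), rep(3L, 4))
  expect_equal(unname(bic$mrna_labels[paste0("ma", 1:7)]), rep("A", 7))

  # permutation invariance of the input rows
  set.seed(36)
  bic2 <- binarize_bicluster(list(edges = edges[sample(nrow(edges)), ]), 3, 3)
  expect_equal(adjusted_rand_index(bic$lnc_labels, bic2$lnc_labels), 1)
  expect_equal(adjusted_rand_index(bic$mrna_labels, bic2$mrna_labels), 1)

  expect_error(binarize_bicluster(list(edges = edges[1:3, ]), 3, 3),
               "not enough|fewer")
})

test_that("cluster annotation reports replicated-call fractions", {
  labels <- stats::setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  cons <- list(table = data.frame(
    gene_id = c("a", "b", "c"),
    logFC_A = c(2, 1, -1), logFC_B = c(2, 1, -1),
    p_adj_A = 0.01, p_adj_B = 0.01,
    status = c("replicated_up_g1", "replicated_up_g1", "replicated_up_g2")))
  ann <- annotate_clusters(labels, list(er = cons))
  expect_equal(ann$frac_up_g1[ann$cluster == 1], 1)
  expect_equal(ann$frac_up_g2[ann$cluster == 2], 0.5)
  expect_equal(ann$frac_unannotated[ann$cluster == 2], 0.5)

  empty <- list(table = cons$table[0, ])
  ann2 <- annotate_clusters(labels, list(er = empty))
  expect_true(all(ann2$frac_up_g1 == 0))
  expect_true(all(ann2$frac_unannotated == 1))
})

test_that("adjusted Rand index behaves at its reference points", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(a[-1], a[1])),
               adjusted_rand_index(c(a[-1], a[1]), a))
  set.seed(37)
  shuffled <- sample(a)
  expect_lt(abs(adjusted_rand_index(a, shuffled)), 0.25)
})
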