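test_that("signature scores are per-sample means over present genes", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expr <- expression_matrix(m, "log2p1")
  one <- signature_score(expr, "g2")
  expect_equal(unname(one$score), c(2, 5))
  all3 <- signature_score(expr, c("g1", "g2", "g3", "absent"))
  expect_equal(unname(all3$score), c(2, 5))
  expect_equal(all3$coverage, 0.75)
  const <- expression_matrix(matrix(3, 2, 2, dimnames = list(c("a", "b"),
                                                             c("s1", "s2"))),
                             "log2p1")
  expect_equal(unname(signature_score(const, c("a", "b"))$score), c(3, 3))
  expect_error(signature_score(expr, "nope"), "no signature gene")
})

test_that("attribution recovers constructed coefficients exactly", {
  set.seed(41)
  n <- 60
  esr1 <- stats::rnorm(n, 5)
  fib <- stats::rnorm(n, 2)
  lym <- stats::rnorm(n, 3)
  zesr1 <- scale(esr1)[, 1]
  lnc <- rbind(pure = 4 + 2 * zesr1 + stats::rnorm(n, 0, 0.01),
               null = stats::rnorm(n, 4))
  colnames(lnc) <- paste0("s", 1:n)
  res <- glm_attribution(expression_matrix(abs(lnc), "log2p1"),
                         esr1, fib, lym)
  expect_equal(res$coef_esr1[res$lnc_id == "pure"], 2, tolerance = 0.02)
  expect_lt(abs(res$coef_fib[res$lnc_id == "pure"]), 0.02)
  expect_equal(res$best_variable[res$lnc_id == "pure"], "ESR1")

  # standardized predictors make the fit scale-invariant
  res2 <- glm_attribution(expression_matrix(abs(lnc), "log2p1"),
                          esr1 * 100 + 3, fib, lym)
  expect_equal(res$coef_esr1, res2$coef_esr1, tolerance = 1e-9)

  # closed-form normal equations oracle on a 12-sample fixture
  set.seed(42)
  n <- 12
  p1 <- stats::rnorm(n); p2 <- stats::rnorm(n); p3 <- stats::rnorm(n)
  y <- matrix(abs(stats::rnorm(n, 5)), 1, n,
              dimnames = list("g", paste0("s", 1:n)))
  res3 <- glm_attribution(expression_matrix(y, "log2p1"), p1, p2, p3)
  X <- cbind(1, scale(cbind(p1, p2, p3)))
  bhat <- solve(t(X) %*% X, t(X) %*% y[1, ])
  expect_equal(c(res3$coef_esr1, res3$coef_fib, res3$coef_lym),
               unname(bhat[2:4]), tolerance = 1e-10)
  lmfit <- summary(stats::lm(y[1, ] ~ scale(cbind(p1, p2, p3))))
  expect_equal(c(res3$p_esr1, res3$p_fib, res3$p_lym),
               unname(lmfit$coefficients[2:4, 4]), tolerance = 1e-10)

  expect_error(glm_attribution(expression_matrix(y, "log2p1"), p1, p1, p3),
               "collinear")
  expect_error(glm_attribution(expression_matrix(y[, 1:8, drop = FALSE],
                                                 "log2p1"),
                               p1[1:8], p2[1:8], p3[1:8]), ">= 10")
})

test_that("cluster coefficient comparison tests and fractions behave", {
  set.seed(43)
  att <- data.frame(
    lnc_id = paste0("l", 1:30),
    coef_esr1 = stats::rnorm(30), coef_fib = stats::rnorm(30),
    coef_lym = stats::rnorm(30),
    p_esr1 = stats::runif(30), p_fib = stats::runif(30),
    p_lym = stats::runif(30),
    best_variable = sample(c("ESR1", "fibroblast", "lymphocyte"), 30, TRUE))
  labels <- stats::setNames(rep(1:3, each = 10), att$lnc_id)
  res <- compare_cluster_coefficients(att, labels)
  expect_gt(min(res$kw$p), 0.001)  # identical distributions: no separation
  expect_equal(nrow(res$fractions), 3L)
  expect_true(all(abs(rowSums(res$fractions[, c("frac_esr1", "frac_fib",
                                                "frac_lym")]) - 1) < 1e-12))

  lab1 <- stats::setNames(rep(1, 30), att$lnc_id)
  expect_error(suppressWarnings(compare_cluster_coefficients(att, lab1)),
               ">= 2 clusters")
  lab_small <- stats::setNames(c(rep(1, 28), 2, 2), att$lnc_id)
  expect_warning(expect_error(compare_cluster_coefficients(att, lab_small)),
                 "excluding")
})

test_that("single-cell log-normalization follows the scale-factor formula", {
  counts <- matrix(c(1, 9999, 0, 500), 2, 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ct <- stats::setNames(c("T", "CAF"), c("c1", "c2"))
  sc <- single_cell_dataset(counts, ct)
  norm <- sc_lognormalize(sc, scale_factor = 10000)
  expect_equal(norm$norm["g1", "c1"], log(2))  # count 1 of total 10000
  expect_equal(norm$norm["g1", "c2"], 0)
  # scale invariance: doubling all counts of a cell changes nothing
  sc2 <- single_cell_dataset(counts * 2, ct)
  expect_equal(sc_lognormalize(sc2)$norm, norm$norm)
  # zero-total cells removed with a warning
  counts0 <- cbind(counts, c3 = c(0, 0))
  sc3 <- single_cell_dataset(counts0, c(ct, c3 = "B"))
  expect_warning(n3 <- sc_lognormalize(sc3), "zero total")
  expect_equal(colnames(n3$norm), c("c1", "c2"))
})

test_that("dot-plot summaries equal a brute-force double loop", {
  set.seed(44)
  counts <- matrix(stats::rpois(20 * 30, 0.8), 20, 30,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  ct <- stats::setNames(rep(c("T", "B", "CAF"), each = 10), colnames(counts))
  sc <- single_cell_dataset(counts, ct)
  norm <- sc_lognormalize(sc)
  genes <- paste0("g", 1:5)
  dots <- dotplot_summary(sc, norm, genes)
  for (g in genes) for (ty in c("T", "B", "CAF")) {
    cells <- names(ct)[ct == ty & names(ct) %in% colnames(norm$norm)]
    row <- dots[dots$gene_id == g & dots$cell_type == ty, ]
    expect_equal(row$pct_expressing, 100 * mean(counts[g, cells] > 0))
    expect_equal(row$mean_norm_expr, mean(norm$norm[g, cells]))
  }
  expect_error(dotplot_summary(sc, norm, "nope"), "absent")
})

test_that("marker tests delegate to the rank-sum test one group vs rest", {
  set.seed(45)
  expr <- matrix(stats::rnorm(5 * 24), 5, 24,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:24)))
  grp <- rep(c("T", "B", "CAF"), each = 8)
  expr["g1", grp == "T"] <- expr["g1", grp == "T"] + 5
  res <- marker_test_one_vs_rest(expr, grp)
  t_res <- res[res$group == "T", ]
  expect_equal(t_res$gene_id[which.min(t_res$p)], "g1")
  expect_gt(t_res$logFC[t_res$gene_id == "g1"], 3)
  # delegation identity with the shared rank-sum operation
  direct <- wilcoxon_ranksum(expr["g2", grp == "B"], expr["g2", grp != "B"])
  expect_equal(res$p[res$group == "B" & res$gene_id == "g2"], direct$p)
  expect_error(marker_test_one_vs_rest(expr, rep("T", 24)), ">= 2 groups")
})
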