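# Two-group differential expression with empirical-Bayes variance moderation
# (hierarchical scaled-chi-square model, method-of-moments hyperparameters),
# cross-cohort consensus calls, and univariate Cox proportional-hazards
# screening with Breslow tie handling.

# Newton inversion of the trigamma function, psi'(y) = x. Uses the standard
# asymptotic starting value 0.5 + 1/x and the update for 1/psi'.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Fits the hierarchical model s_g^2 ~ s0^2 * chi^2_df / df with prior
#' 1/sigma_g^2 ~ chi^2_d0 by the method of moments on log s_g^2: with
#' e_g = log(s_g^2) - digamma(df/2) + log(df/2), the prior degrees of freedom
#' solve trigamma(d0/2) = var(e) - trigamma(df/2) and
#' s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). Zero sample variances are
#' excluded from estimation.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (shared scalar).
#' @return list with `d0` (prior df, possibly Inf) and `s0_sq` (prior variance).
#' @export
fit_fdist_moments <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need >= 2 positive variances to estimate the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1)
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated-t two-group differential expression
#'
#' Per gene, an ordinary two-group fit gives the mean difference (group1 -
#' group2, the log fold change on log2(TPM+1) data) and pooled residual
#' variance. Variances are shrunk toward an empirically estimated prior:
#' s~_g^2 = (d0 s0^2 + df s_g^2) / (d0 + df), the moderated t is
#' logFC / (s~_g sqrt(1/n1 + 1/n2)) on df + d0 degrees of freedom, and
#' p-values are BH-adjusted across genes.
#'
#' @param expr ExpressionMatrix in log2p1, genes pre-filtered.
#' @param groups vector of two labels over samples (character or factor);
#'   `group1` names the level whose mean enters positively.
#' @param group1 label treated as group 1; default: first sorted level.
#' @param d0_override optional forced prior df (0 = ordinary t, Inf = prior
#'   variance only); NULL estimates it from the data.
#' @return list with `table` (data.frame: gene_id, logFC, t_mod, p, p_adj,
#'   direction) and `params` (d0, s0_sq, residual_df).
#' @export
moderated_t_de <- function(expr, groups, group1 = NULL, d0_override = NULL) {
  stopifnot_unit(expr, "log2p1")
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("groups must have one label per sample")
  keep <- !is.na(groups)
  m <- unclass(expr)[, keep, drop = FALSE]
  groups <- groups[keep]
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("need exactly two groups, got: ", paste(lev, collapse = ", "))
  if (is.null(group1)) group1 <- lev[1]
  g1 <- groups == group1
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples (", n1, "/", n2, ")")
  df <- n1 + n2 - 2
  mu1 <- rowMeans(m[, g1, drop = FALSE])
  mu2 <- rowMeans(m[, !g1, drop = FALSE])
  beta <- mu1 - mu2
  ss1 <- rowSums((m[, g1, drop = FALSE] - mu1)^2)
  ss2 <- rowSums((m[, !g1, drop = FALSE] - mu2)^2)
  s2 <- (ss1 + ss2) / df
  if (is.null(d0_override)) {
    prior <- fit_fdist_moments(s2, df)
  } else {
    if (d0_override < 0) stop("d0_override must be >= 0")
    base <- if (any(is.finite(s2) & s2 > 0)) fit_fdist_moments(s2, df) else list(s0_sq = 1)
    prior <- list(d0 = d0_override, s0_sq = base$s0_sq)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  # genes with exactly zero residual variance fall back to the prior variance
  s2_post[s2 == 0] <- s0_sq
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- beta / se
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = if (is.infinite(df_total)) Inf else df_total)
  p <- pmax(p, .Machine$double.xmin)
  tab <- data.frame(gene_id = rownames(m), logFC = beta, t_mod = t_mod,
                    p = p, p_adj = bh_adjust(p),
                    direction = ifelse(beta >= 0, "up_in_g1", "up_in_g2"),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       params = list(d0 = d0, s0_sq = s0_sq, residual_df = df,
                     n1 = n1, n2 = n2, group1 = group1,
                     group2 = setdiff(lev, group1)))
}

#' Cross-cohort consensus of two differential-expression tables
#'
#' A gene replicates iff it is significant (adjusted p < alpha) in both
#' cohorts with the same fold-change sign; genes significant in both with
#' opposite signs are flagged discordant and excluded from the replicated
#' sets. Reports the Pearson correlation of logFC over genes significant in
#' both cohorts (discordant included, as the cross-cohort concordance view).
#'
#' @param deA,deB `table` components from [moderated_t_de()] (same contrast,
#'   same group1).
#' @param alpha significance threshold on adjusted p.
#' @return list with `table` (gene_id, logFC_A, logFC_B, p_adj_A, p_adj_B,
#'   status in replicated_up_g1 / replicated_up_g2 / discordant /
#'   not_replicated) and `concordance_r`.
#' @export
cross_cohort_consensus <- function(deA, deB, alpha = 0.05) {
  shared <- intersect(deA$gene_id, deB$gene_id)
  if (length(shared) == 0) stop("no shared genes between cohorts")
  a <- deA[match(shared, deA$gene_id), ]
  b <- deB[match(shared, deB$gene_id), ]
  sigA <- a$p_adj < alpha
  sigB <- b$p_adj < alpha
  same_sign <- sign(a$logFC) == sign(b$logFC)
  status <- rep("not_replicated", length(shared))
  status[sigA & sigB & !same_sign] <- "discordant"
  status[sigA & sigB & same_sign & a$logFC > 0] <- "replicated_up_g1"
  status[sigA & sigB & same_sign & a$logFC < 0] <- "replicated_up_g2"
  both_sig <- sigA & sigB
  r <- if (sum(both_sig) >= 3) stats::cor(a$logFC[both_sig], b$logFC[both_sig]) else NA_real_
  list(table = data.frame(gene_id = shared, logFC_A = a$logFC, logFC_B = b$logFC,
                          p_adj_A = a$p_adj, p_adj_B = b$p_adj, status = status,
                          stringsAsFactors = FALSE),
       concordance_r = r,
       n_replicated = sum(startsWith(status, "replicated")),
       n_discordant = sum(status == "discordant"))
}

# Breslow partial log-likelihood, score and information for one covariate.
cox_breslow_derivs <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- x * beta
  w <- exp(eta)
  # reverse cumulative sums give risk-set aggregates at each time
  S0 <- rev(cumsum(rev(w)))
  S1 <- rev(cumsum(rev(w * x)))
  S2 <- rev(cumsum(rev(w * x^2)))
  # Breslow: each event uses the risk set of its own time; ties share the set
  first_at <- match(time, time)  # index of first subject with this time
  ev <- which(event == 1)
  ri <- first_at[ev]
  ll <- sum(eta[ev] - log(S0[ri]))
  score <- sum(x[ev] - S1[ri] / S0[ri])
  info <- sum(S2[ri] / S0[ri] - (S1[ri] / S0[ri])^2)
  list(ll = ll, score = score, info = info)
}

#' Univariate Cox proportional-hazards fit (Breslow ties)
#'
#' Maximizes the single-covariate partial likelihood by Newton-Raphson with
#' step halving; the standard error comes from the observed information and
#' the p-value is the Wald test.
#'
#' @param x numeric covariate (e.g. one gene's expression).
#' @param os_time follow-up times.
#' @param os_event event indicators (1 = death, 0 = censored).
#' @param max_iter,tol Newton controls.
#' @return list with `beta`, `se`, `p`, `ll`, `converged`.
#' @export
cox_univariate <- function(x, os_time, os_event, max_iter = 25, tol = 1e-9) {
  ok <- !is.na(x) & !is.na(os_time) & !is.na(os_event)
  x <- x[ok]; os_time <- os_time[ok]; os_event <- os_event[ok]
  if (sum(os_event) == 0) stop("no events")
  if (stats::sd(x) == 0) stop("constant covariate")
  beta <- 0
  converged <- FALSE
  d <- cox_breslow_derivs(beta, os_time, os_event, x)
  for (iter in seq_len(max_iter)) {
    if (d$info <= 0) break
    step <- d$score / d$info
    # step halving keeps the likelihood non-decreasing
    for (h in 0:10) {
      cand <- beta + step / 2^h
      dn <- cox_breslow_derivs(cand, os_time, os_event, x)
      if (is.finite(dn$ll) && dn$ll >= d$ll - 1e-12) break
    }
    delta <- cand - beta
    beta <- cand; d <- dn
    if (abs(delta) < tol) { converged <- TRUE; break }
    if (abs(beta) > 15) break  # monotone likelihood: no finite maximum
  }
  se <- 1 / sqrt(d$info)
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)), ll = d$ll,
       converged = converged)
}

#' Per-gene Cox screen within strata
#'
#' Runs [cox_univariate()] on the standardized expression of every gene,
#' separately within each stratum (e.g. ER+ and ER- patients), and
#' BH-adjusts p-values per stratum.
#'
#' @param expr ExpressionMatrix in log2p1.
#' @param clin ClinicalTable with os_time/os_event covering the samples.
#' @param strata optional vector over samples (e.g. ER status); NA samples
#'   are dropped. NULL = one stratum.
#' @return data.frame: stratum, gene_id, beta, se, p, p_adj, converged.
#' @export
cox_screen <- function(expr, clin, strata = NULL) {
  stopifnot_unit(expr, "log2p1")
  clin <- clin[match(colnames(expr), clin$sample_id), ]
  if (is.null(strata)) strata <- rep("all", ncol(expr))
  out <- list()
  for (s in sort(unique(strata[!is.na(strata)]))) {
    sel <- which(!is.na(strata) & strata == s &
                   !is.na(clin$os_time) & !is.na(clin$os_event))
    m <- unclass(expr)[, sel, drop = FALSE]
    res <- lapply(rownames(m), function(g) {
      x <- m[g, ]
      if (stats::sd(x) == 0)
        return(data.frame(stratum = s, gene_id = g, beta = NA_real_,
                          se = NA_real_, p = NA_real_, converged = FALSE))
      fit <- cox_univariate(scale(x)[, 1], clin$os_time[sel], clin$os_event[sel])
      data.frame(stratum = s, gene_id = g, beta = fit$beta, se = fit$se,
                 p = fit$p, converged = fit$converged)
    })
    tab <- do.call(rbind, res)
    tab$p_adj <- NA_real_
    okp <- !is.na(tab$p)
    tab$p_adj[okp] <- bh_adjust(pmax(tab$p[okp], .Machine$double.xmin))
    out[[s]] <- tab
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
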