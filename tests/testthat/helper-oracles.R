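# Independent oracles used to validate the statistical and interval
# operations. These are deliberately written from first principles
# (enumeration, closed forms, naive double loops) and share no code with the
# implementations they check.

# upper-tail hypergeometric P(X >= k) by direct PMF summation
oracle_hypergeom_upper <- function(k, m, N, q) {
  lo <- max(0, q - (N - m))
  hi <- min(m, q)
  if (k > hi) return(0)
  ks <- max(k, lo):hi
  sum(choose(m, ks) * choose(N - m, q - ks)) / choose(N, q)
}

# one-sided (greater) Fisher exact p by enumeration over the conditional
# hypergeometric support of cell a given fixed margins
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  sum(probs[(lo:hi) >= a])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_wilcoxon_exact <- function(x, y, alternative = "two.sided") {
  n <- length(x) + length(y)
  vals <- c(x, y)
  idx <- utils::combn(n, length(x))
  ranks <- rank(vals)
  u_of <- function(sel) sum(ranks[sel]) - length(x) * (length(x) + 1) / 2
  u_obs <- u_of(seq_len(length(x)))
  us <- apply(idx, 2, u_of)
  mu <- length(x) * length(y) / 2
  switch(alternative,
         two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12),
         greater = mean(us >= u_obs - 1e-12),
         less = mean(us <= u_obs + 1e-12))
}

# Kruskal-Wallis H with tie correction, straight from the formula
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2,
               numeric(1)))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# hand-rolled BH step-up: max_i>=j p(i) n / i with cumulative minimum
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * n / (n:1)))[ro]
}

# method-of-moments hyperparameters via uniroot on the trigamma equation
# (independent of the package's Newton-based trigamma inverse)
oracle_moments <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (excess <= 0) return(list(d0 = Inf, s0_sq = exp(emean)))
  half_d0 <- stats::uniroot(function(y) trigamma(y) - excess,
                            lower = 1e-8, upper = 1e8, tol = 1e-14)$root
  list(d0 = 2 * half_d0, s0_sq = exp(emean + digamma(half_d0) - log(half_d0)))
}

# Breslow partial log-likelihood computed naively (explicit risk sets)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  lls <- vapply(grid, oracle_cox_loglik, numeric(1),
                time = time, event = event, x = x)
  grid[which.max(lls)]
}

# Spearman rho from explicit average ranks and the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# interval brute force: does [s1,e1) overlap [s2,e2) on the same chrom?
bf_overlaps <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1

# per-query any-hit flags against a subject interval table
bf_any_hit <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i)
    any(bf_overlaps(query$chrom[i], query$start[i], query$end[i],
                    subject$chrom, subject$start, subject$end)), logical(1))
}

# Ward.D2 agglomeration by the Lance-Williams update, tracking merge heights
oracle_ward_d2 <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  diag(dm) <- Inf
  while (length(active) > 1) {
    sub <- dm[active, active, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    hij <- dm[i, j]
    heights <- c(heights, hij)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      dm[i, k] <- dm[k, i] <- sqrt(((ni + nk) * dm[i, k]^2 +
                                      (nj + nk) * dm[j, k]^2 -
                                      nk * hij^2) / (ni + nj + nk))
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    dm[j, ] <- dm[, j] <- Inf
  }
  sort(heights)
}
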