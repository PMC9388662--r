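# Exact small-sample statistics shared by every enrichment stage. These are
# deliberately thin, contract-enforcing wrappers over the base R tests
# (phyper, fisher.test, wilcox.test, kruskal.test, p.adjust); the test suite
# checks them against exhaustive enumeration oracles.

#' Hypergeometric over-representation of terms in a query set
#'
#' Upper-tail hypergeometric test P(X >= k) for each term against a fixed
#' universe, with Benjamini-Hochberg adjustment across terms. Terms supported
#' by fewer than `min_support` query members are excluded before testing.
#'
#' @param query character vector of ids, must be a subset of `universe`.
#' @param terms named list of character id vectors (each intersected with the
#'   universe before testing).
#' @param universe character vector of all ids under consideration.
#' @param min_support minimum query overlap for a term to be tested.
#' @return data.frame with term_id, overlap_count, query_size, term_size,
#'   universe_size, ratio (fold enrichment), p, p_adj; one row per tested
#'   term, ordered by p.
#' @export
hypergeom_enrich <- function(query, terms, universe, min_support = 0) {
  universe <- unique(universe)
  query <- unique(query)
  off <- setdiff(query, universe)
  if (length(off))
    stop("query ids outside the universe: ", paste(utils::head(off, 10), collapse = ", "))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(terms), function(tid) {
    term <- intersect(unique(terms[[tid]]), universe)
    m <- length(term)
    k <- length(intersect(term, query))
    if (k < min_support || m == 0) return(NULL)
    # P(X >= k): upper tail including the observed overlap
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    ratio <- if (q > 0 && m > 0) (k / q) / (m / N) else 0
    data.frame(term_id = tid, overlap_count = k, query_size = q, term_size = m,
               universe_size = N, ratio = ratio, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), overlap_count = integer(),
                      query_size = integer(), term_size = integer(),
                      universe_size = integer(), ratio = numeric(),
                      p = numeric(), p_adj = numeric()))
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional exact test given the margins; the default alternative is
#' one-sided enrichment ("greater").
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (a = in-group & hit, b = in-group & miss, c = out-group & hit,
#'   d = out-group & miss).
#' @param alternative "greater", "less" or "two.sided".
#' @return list with `odds_ratio` (sample odds ratio ad/bc) and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero 2x2 table")
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- (a * d) / (b * c)  # sample odds ratio; 0/0 -> NaN, x/0 -> Inf
  list(odds_ratio = or, p = unname(ft$p.value))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when the combined sample size is <= 30 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param alternative as in [stats::wilcox.test()].
#' @return list with `statistic` (the Mann-Whitney U for `x`) and `p`.
#' @export
wilcoxon_ranksum <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 30) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value))
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups list (>= 2 elements) of non-empty numeric samples.
#' @return list with `H` (tie-corrected statistic), `df`, `p` (chi-square).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)  # fully tied data carry no rank information
    return(list(H = 0, df = length(groups) - 1, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = unname(kt$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH with monotonicity enforcement; errors on p-values
#' outside (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment with explicit family size
#'
#' @param p raw p-values.
#' @param m family size; warns if smaller than `length(p)`.
#' @return elementwise `min(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (m < length(p))
    warning("m (", m, ") is smaller than the number of p-values (", length(p), ")")
  pmin(1, p * m)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (term, description, members...; tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}
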