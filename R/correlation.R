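#' Correlation between two effect-size vectors
#'
#' Pearson product-moment correlation, or Spearman's rank correlation
#' (Pearson on average-ranked data, ties receiving average ranks).
#'
#' @param x,y numeric vectors of equal length (>= 3, finite)
#' @param method `"pearson"` or `"spearman"`
#' @return correlation coefficient
#' @export
#' @examples
#' correlate(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman")  # 0.8
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop_validation("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("non-finite values in correlation input")
  }
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_validation("correlation undefined: zero variance in input")
  }
  stats::cor(x, y)
}

#' Large-sample standard error of a correlation coefficient
#'
#' `se = sqrt((1 - r^2) / df)` with `df = n - 2`.
#'
#' @param r correlation coefficient in `[-1, 1]`
#' @param df degrees of freedom (shared phenotypes minus 2), >= 1
#' @return standard error
#' @export
#' @examples
#' corr_se(0.81, 73)  # ~0.069
corr_se <- function(r, df) {
  stopifnot(all(abs(r) <= 1))
  if (any(df < 1)) stop_validation("df must be >= 1")
  sqrt((1 - r^2) / df)
}

#' Two-sided p value for a correlation coefficient
#'
#' Student-t test: `t = r * sqrt(df / (1 - r^2))`, two-sided tail of the
#' t distribution with `df` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @inheritParams corr_se
#' @return two-sided p value
#' @export
corr_pvalue <- function(r, df) {
  stopifnot(all(abs(r) <= 1))
  if (any(df < 1)) stop_validation("df must be >= 1")
  p <- ifelse(abs(r) == 1, 0, {
    tt <- abs(r) * sqrt(df / (1 - r^2))
    2 * stats::pt(tt, df, lower.tail = FALSE)
  })
  unname(p)
}

#' Bonferroni adjustment
#'
#' @param p p value(s) in `[0, 1]`
#' @param m number of tests (>= 1)
#' @return `min(1, m * p)`
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Permutation p value for a profile correlation
#'
#' Shuffles the second vector uniformly at random `n_perm` times,
#' recomputing the correlation each time, and returns the add-one
#' empirical two-sided p value
#' `(1 + #\{|r*| >= |r_obs|\}) / (n_perm + 1)`, bounded below by
#' `1/(n_perm + 1)` (1/10001 < 1e-4 at the default 10,000 shuffles).
#' With `exhaustive = TRUE` (vectors of length <= 8) all `n!`
#' permutations are enumerated and the exact proportion
#' `#\{|r*| >= |r_obs|\} / n!` is returned instead.
#'
#' @inheritParams correlate
#' @param n_perm number of random shuffles (>= 1)
#' @param seed integer seed; the caller's RNG state is left untouched
#' @param exhaustive enumerate all permutations instead of sampling
#' @return empirical p value
#' @export
permutation_pvalue <- function(x, y, n_perm = 10000L, seed = 1L,
                               method = c("pearson", "spearman"),
                               exhaustive = FALSE) {
  method <- match.arg(method)
  r_obs <- correlate(x, y, method = method)
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  # after ranking, Spearman is plain Pearson, so shuffles only permute y
  thr <- abs(r_obs) - 1e-12
  if (exhaustive) {
    n <- length(x)
    if (n > 8L) stop_validation("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, function(idx) stats::cor(x, y[idx]))
    return(mean(abs(rs) >= thr))
  }
  stopifnot(n_perm >= 1L)
  xc <- x - mean(x)
  denom_x <- sqrt(sum(xc^2))
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      ys <- sample(y)
      r <- sum(xc * (ys - mean(ys))) / (denom_x * sqrt(sum((ys - mean(ys))^2)))
      abs(r) >= thr
    }, logical(1)))
  })
  (1 + hits) / (n_perm + 1)
}

# all n! permutations of 1:n as a matrix (rows); n <= 8
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Pairwise cross-disorder correlation table
#'
#' Computes, for every unordered pair of disorders in the panel, the
#' correlation between their effect-size profiles over the shared
#' phenotypes, with analytic standard error and Student-t p value,
#' Bonferroni adjustment over all pairs, and a permutation p value from
#' random shuffling of one profile.  Rows are sorted by ascending p.
#' Each pair draws its shuffles from a private stream seeded
#' deterministically from the master seed and the pair labels, so results
#' do not depend on evaluation order.
#'
#' @param panel a [disorder_panel()]
#' @param method correlation method (default Pearson, matching the
#'   published cross-disorder tables)
#' @param n_perm permutation count per pair (default 10,000)
#' @param seed master seed for the permutation streams
#' @param m number of tests for the Bonferroni column; default the number
#'   of pairs
#' @return data frame of class `pairwise_table` with columns `disorder1`,
#'   `disorder2`, `pair`, `r`, `n_overlap`, `df`, `se`, `p`, `p_bonf`,
#'   `p_perm`, `n_perm`, `method`
#' @export
pairwise_table <- function(panel, method = c("pearson", "spearman"),
                           n_perm = 10000L, seed = 1L, m = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "disorder_panel"))
  labs <- panel_disorders(panel)
  pairs <- utils::combn(labs, 2L)
  m <- m %||% ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    # canonical (sorted-label) orientation: the permutation stream shuffles
    # the second profile, so results must not depend on panel order
    lab <- sort(pairs[, j])
    a <- panel$profiles[[lab[1]]]
    b <- panel$profiles[[lab[2]]]
    xy <- intersect_phenotypes(a, b)
    r <- correlate(xy$d_a, xy$d_b, method = method)
    n <- attr(xy, "n_overlap")
    df <- n - 2L
    key <- pair_key(a$disorder, b$disorder)
    data.frame(
      disorder1 = a$disorder, disorder2 = b$disorder, pair = key,
      r = r, n_overlap = n, df = df,
      se = corr_se(r, df), p = corr_pvalue(r, df),
      p_bonf = NA_real_,
      p_perm = permutation_pvalue(xy$d_a, xy$d_b, n_perm = n_perm,
                                  seed = derive_seed(seed, key),
                                  method = method),
      n_perm = n_perm, method = method,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p, m)
  out <- out[order(out$p, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m_tests") <- m
  attr(out, "seed") <- seed
  class(out) <- c("pairwise_table", "data.frame")
  out
}

#' Write a pairwise table as TSV
#'
#' p columns are printed in scientific notation with 3 significant digits
#' alongside full-precision companion columns.
#'
#' @param tab a `pairwise_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pairwise_table <- function(tab, path) {
  out <- data.frame(
    disorder1 = tab$disorder1, disorder2 = tab$disorder2,
    r = sprintf("%.4f", tab$r), df = tab$df, se = sprintf("%.3f", tab$se),
    p = format_pval(tab$p), p_bonf = format_pval(tab$p_bonf),
    p_perm = format_pval(tab$p_perm), n_perm = tab$n_perm,
    method = tab$method,
    p_precise = sprintf("%.17g", tab$p),
    p_bonf_precise = sprintf("%.17g", tab$p_bonf),
    p_perm_precise = sprintf("%.17g", tab$p_perm),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise correlations of a panel as a pair-keyed vector
#'
#' Lightweight companion to [pairwise_table()] for workflows that only
#' need the correlation coefficients (e.g. simulation studies of the
#' correlation of correlations): no permutation test is run.
#'
#' @inheritParams pairwise_table
#' @return named numeric vector of correlations keyed by [pair_key()]
#' @export
panel_pair_correlations <- function(panel, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "disorder_panel"))
  pairs <- utils::combn(panel_disorders(panel), 2L)
  out <- vapply(seq_len(ncol(pairs)), function(j) {
    xy <- intersect_phenotypes(panel$profiles[[pairs[1, j]]],
                               panel$profiles[[pairs[2, j]]])
    correlate(xy$d_a, xy$d_b, method = method)
  }, numeric(1))
  names(out) <- pair_key(pairs[1, ], pairs[2, ])
  out
}
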