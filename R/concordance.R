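# correlation-of-correlations between the imaging and genetic similarity
# structures, with leave-one-out sensitivity

# coerce a pair -> value mapping to a named numeric vector keyed by pair_key.
# Accepts: a named numeric vector, a pairwise_table (uses r), an rg table
# (disorder1/disorder2/rg), or any data frame with disorder1/disorder2 and
# a single value column.
as_pair_vector <- function(x, value_col = NULL) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(x[order(names(x))])
  }
  if (is.data.frame(x)) {
    if (is.null(value_col)) {
      value_col <- intersect(c("r", "rg", "value"), names(x))[1]
      if (is.na(value_col)) {
        stop_validation("cannot find a value column ('r', 'rg' or 'value')")
      }
    }
    keys <- pair_key(x$disorder1, x$disorder2)
    if (anyDuplicated(keys)) {
      stop_validation("duplicate pair(s): %s",
                      paste(unique(keys[duplicated(keys)]), collapse = ", "))
    }
    v <- stats::setNames(x[[value_col]], keys)
    return(v[order(names(v))])
  }
  stop_validation("expected a named numeric vector or a pair table")
}

align_pairs <- function(imaging, genetic) {
  iv <- as_pair_vector(imaging)
  gv <- as_pair_vector(genetic)
  miss_g <- setdiff(names(iv), names(gv))
  miss_i <- setdiff(names(gv), names(iv))
  if (length(miss_g) || length(miss_i)) {
    stop_validation(
      "pair sets differ: missing from genetic: {%s}; missing from imaging: {%s}",
      paste(miss_g, collapse = ", "), paste(miss_i, collapse = ", "))
  }
  list(imaging = iv, genetic = gv[names(iv)])
}

#' Correlation of correlations
#'
#' Rank-correlates the vector of pairwise imaging-profile correlations with
#' the vector of pairwise genetic correlations over the same disorder
#' pairs.  Pairs are aligned by disorder labels, never by position.  The
#' p value uses the Student-t approximation on `n_pairs - 2` degrees of
#' freedom by default; an exact permutation test over pair labels is
#' available.
#'
#' @param imaging pair-to-correlation mapping: a named numeric vector
#'   keyed by [pair_key()], or a [pairwise_table()] (its `r` column is used)
#' @param genetic pair-to-rg mapping: named vector or a genetic-correlation
#'   table with columns `disorder1`, `disorder2`, `rg`
#' @param method correlation method; default Spearman
#' @param p_method `"t"` for the t-approximation, `"permutation"` for an
#'   exact/Monte-Carlo permutation p over pair labels
#' @param n_perm permutation count when `p_method = "permutation"`
#' @param seed seed for the permutation p
#' @param loo also compute leave-one-out diagnostics (needs >= 5 pairs)
#' @return object of class `concordance_result`: list with `rho`, `p`,
#'   `n_pairs`, `method`, and `loo` (named vector of recomputed rho per
#'   excluded pair, with attributes `min`/`max`)
#' @export
correlation_of_correlations <- function(imaging, genetic,
                                        method = c("spearman", "pearson"),
                                        p_method = c("t", "permutation"),
                                        n_perm = 10000L, seed = 1L,
                                        loo = TRUE) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  al <- align_pairs(imaging, genetic)
  n <- length(al$imaging)
  if (n < 4L) stop_validation("need >= 4 pairs, got %d", n)
  rho <- correlate(al$imaging, al$genetic, method = method)
  p <- if (p_method == "t") {
    corr_pvalue(rho, n - 2L)
  } else {
    permutation_pvalue(unname(al$imaging), unname(al$genetic),
                       n_perm = n_perm, seed = seed, method = method)
  }
  loo_v <- if (loo && n >= 5L) leave_one_out(al$imaging, al$genetic, method = method)
  structure(list(rho = rho, p = p, n_pairs = n, method = method,
                 p_method = p_method, loo = loo_v),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s rho = %.3f, p = %.3g over %d pairs\n",
              x$method, x$rho, x$p, x$n_pairs))
  if (!is.null(x$loo)) {
    cat(sprintf("  leave-one-out rho range: %.3f to %.3f\n",
                attr(x$loo, "min"), attr(x$loo, "max")))
  }
  invisible(x)
}

#' Leave-one-out sensitivity of the correlation of correlations
#'
#' Excludes each disorder pair in turn and recomputes the rank correlation
#' on the remaining pairs, flagging whether the association is driven by a
#' single pair.
#'
#' @inheritParams correlation_of_correlations
#' @return named numeric vector (one entry per excluded pair) with
#'   attributes `min` and `max`
#' @export
leave_one_out <- function(imaging, genetic, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  al <- align_pairs(imaging, genetic)
  n <- length(al$imaging)
  if (n < 5L) stop_validation("leave-one-out needs >= 5 pairs, got %d", n)
  out <- vapply(seq_len(n), function(i) {
    correlate(al$imaging[-i], al$genetic[-i], method = method)
  }, numeric(1))
  names(out) <- names(al$imaging)
  attr(out, "min") <- min(out)
  attr(out, "max") <- max(out)
  out
}
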