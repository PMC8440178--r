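# per-phenotype cross-disorder statistics: sign concordance, Cochran's Q
# heterogeneity, and per-disorder profile summaries

#' Exact binomial sign test across disorders
#'
#' Tests whether the number of disorders sharing the same direction of
#' effect for one phenotype exceeds chance (null probability 0.5).  Zero
#' effect sizes are excluded from the trial count and reported as
#' `n_zero`.  The two-sided p is the doubled smaller tail of the exact
#' binomial, capped at 1.
#'
#' @param d numeric vector of Cohen's d across disorders (>= 2 nonzero)
#' @return list with `n_negative`, `n_positive`, `n_zero`, `p`
#' @export
#' @examples
#' sign_test(rep(-0.1, 7))$p  # 2 * 0.5^7 = 0.015625
sign_test <- function(d) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  n_neg <- sum(d < 0)
  n_pos <- sum(d > 0)
  n_zero <- sum(d == 0)
  n <- n_neg + n_pos
  if (n < 2L) stop_validation("sign test undefined: fewer than 2 nonzero values")
  k <- max(n_neg, n_pos)
  # doubled upper tail P(X >= k) at p = 0.5
  p <- min(1, 2 * stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
  list(n_negative = n_neg, n_positive = n_pos, n_zero = n_zero, p = p)
}

#' Large-sample sampling variance of Cohen's d
#'
#' Standard meta-analytic variance of a standardized mean difference:
#' `v = (n1 + n2)/(n1 * n2) + d^2 / (2 * (n1 + n2))`.
#'
#' @param d Cohen's d
#' @param n_cases,n_controls group sizes (>= 2)
#' @return sampling variance
#' @export
d_sampling_variance <- function(d, n_cases, n_controls) {
  if (any(n_cases < 2) || any(n_controls < 2)) {
    stop_validation("group sizes must be >= 2")
  }
  (n_cases + n_controls) / (n_cases * n_controls) +
    d^2 / (2 * (n_cases + n_controls))
}

#' Cochran's Q heterogeneity test
#'
#' Inverse-variance-weighted heterogeneity of k effect sizes:
#' `Q = sum(w * (d - dbar_w)^2)` with `w = 1/v` and weighted mean
#' `dbar_w`; under homogeneity Q is chi-square with `k - 1` df.
#'
#' @param d effect sizes (length k >= 2)
#' @param v aligned sampling variances (> 0)
#' @return list with `Q`, `df`, `p`
#' @export
#' @examples
#' cochran_q(c(0, 0.4), c(0.01, 0.01))$Q  # 8
cochran_q <- function(d, v) {
  if (length(d) != length(v)) {
    stop_validation("effect sizes and variances differ in length (%d vs %d)",
                    length(d), length(v))
  }
  stopifnot(length(d) >= 2L, all(is.finite(d)), all(is.finite(v)))
  if (any(v <= 0)) stop_validation("sampling variances must be > 0")
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  Q <- sum(w * (d - dbar)^2)
  df <- length(d) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Mean effect size of a profile
#'
#' Arithmetic mean Cohen's d over present phenotypes and its standard
#' error `sd/sqrt(n)`.
#'
#' @param profile an [effect_size_profile()]
#' @return list with `disorder`, `mean_d`, `se_mean`, `n`
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "effect_size_profile"))
  d <- profile$values$d
  if (length(d) < 2L) stop_validation("profile summary needs >= 2 phenotypes")
  list(disorder = profile$disorder, mean_d = mean(d),
       se_mean = stats::sd(d) / sqrt(length(d)), n = length(d))
}

#' Sign-concordance table over all phenotypes of a panel
#'
#' @param panel a [disorder_panel()]
#' @return data frame `region`, `measure`, `phenotype`, `n_disorders`,
#'   `n_neg`, `n_pos`, `n_zero`, `p_sign`; phenotypes with fewer than two
#'   nonzero effect sizes are omitted
#' @export
region_sign_table <- function(panel) {
  stopifnot(inherits(panel, "disorder_panel"))
  ph <- phenotype_registry(panel$registry)
  rows <- lapply(seq_len(nrow(ph)), function(i) {
    d <- phenotype_values(panel, ph$phenotype[i])
    if (sum(d != 0) < 2L) return(NULL)
    st <- sign_test(d)
    data.frame(region = ph$region[i], measure = ph$measure[i],
               phenotype = ph$phenotype[i], n_disorders = length(d),
               n_neg = st$n_negative, n_pos = st$n_positive,
               n_zero = st$n_zero, p_sign = st$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cochran's Q table over all phenotypes of a panel
#'
#' Sampling variances come from the measure-type-specific case/control
#' counts carried by each profile.  Disorders lacking counts for a
#' phenotype's measure are excluded from that phenotype's Q; phenotypes
#' left with fewer than two contributing disorders are skipped and listed
#' in the `skipped` attribute.
#'
#' @param panel a [disorder_panel()]
#' @return data frame `region`, `measure`, `phenotype`, `k`, `Q`, `df`,
#'   `p_q`, with attribute `skipped` (character vector of phenotype ids)
#' @export
region_q_table <- function(panel) {
  stopifnot(inherits(panel, "disorder_panel"))
  ph <- phenotype_registry(panel$registry)
  skipped <- character(0)
  rows <- lapply(seq_len(nrow(ph)), function(i) {
    dv <- phenotype_effects_with_variance(panel, ph$region[i], ph$measure[i])
    if (nrow(dv) < 2L) {
      if (any(!is.na(phenotype_values(panel, ph$phenotype[i], na_ok = TRUE)))) {
        skipped <<- c(skipped, ph$phenotype[i])
      }
      return(NULL)
    }
    q <- cochran_q(dv$d, dv$v)
    data.frame(region = ph$region[i], measure = ph$measure[i],
               phenotype = ph$phenotype[i], k = nrow(dv),
               Q = q$Q, df = q$df, p_q = q$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region = character(0), measure = character(0),
                      phenotype = character(0), k = integer(0),
                      Q = numeric(0), df = integer(0), p_q = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# all disorders' d for one phenotype (present profiles only)
phenotype_values <- function(panel, phenotype, na_ok = FALSE) {
  v <- vapply(panel$profiles, function(p) {
    i <- match(phenotype, p$values$phenotype)
    if (is.na(i)) NA_real_ else p$values$d[i]
  }, numeric(1))
  if (na_ok) v else v[!is.na(v)]
}

phenotype_effects_with_variance <- function(panel, region, measure) {
  phen <- paste(region, measure, sep = ":")
  rows <- lapply(panel$profiles, function(p) {
    i <- match(phen, p$values$phenotype)
    if (is.na(i)) return(NULL)
    n1 <- if (is.null(p$n_cases)) NA_real_ else unname(p$n_cases[measure])
    n2 <- if (is.null(p$n_controls)) NA_real_ else unname(p$n_controls[measure])
    if (is.na(n1) || is.na(n2)) return(NULL)
    data.frame(disorder = p$disorder, d = p$values$d[i],
               v = d_sampling_variance(p$values$d[i], n1, n2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(disorder = character(0), d = numeric(0),
                                      v = numeric(0))
  out
}

#' Per-disorder profile summaries for a panel
#'
#' @param panel a [disorder_panel()]
#' @return data frame `disorder`, `n_phenotypes`, `mean_d`, `se_mean`
#' @export
panel_summary <- function(panel) {
  rows <- lapply(panel$profiles, function(p) {
    s <- profile_summary(p)
    data.frame(disorder = s$disorder, n_phenotypes = s$n,
               mean_d = s$mean_d, se_mean = s$se_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
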