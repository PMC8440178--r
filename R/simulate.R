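# Simulators for every input the pipeline consumes: effect-size panels
# with a target cross-disorder correlation structure, GWAS summary
# statistic pairs with target heritabilities and genetic correlation, and
# a joint scenario coupling the two similarity structures.

#' Default disorder labels of the simulated study design
#' @return character vector of 7 disorder labels
#' @export
default_disorders <- function() {
  c("ADHD", "ASD", "BD", "Epilepsy", "MDD", "OCD", "SCZ")
}

#' Panel scenario: ground truth for a simulated effect-size panel
#'
#' Describes the multivariate-normal generator behind a disorder panel:
#' for each phenotype an independent D-vector of Cohen's d values is
#' drawn with per-disorder means and scales and the given cross-disorder
#' correlation matrix, after which per-disorder phenotype masks are
#' applied.
#'
#' @param disorders disorder labels (length D >= 2)
#' @param target_corr D x D symmetric positive-semidefinite correlation
#'   matrix (unit diagonal)
#' @param means,scales per-disorder location and scale of the d values
#'   (recycled if scalar; scales > 0)
#' @param masks named list of phenotype ids to EXCLUDE per disorder (see
#'   [phenotype_registry()]); pairs must keep >= 3 shared phenotypes
#' @param n_table optional data frame `disorder`, `measure`, `n_cases`,
#'   `n_controls` attached to the generated profiles
#' @param seed integer seed
#' @param registry phenotype registry
#' @return object of class `panel_scenario`
#' @export
panel_scenario <- function(disorders, target_corr, means = 0, scales = 0.1,
                           masks = list(), n_table = NULL, seed = 1L,
                           registry = brain_registry()) {
  d <- length(disorders)
  stopifnot(d >= 2L, !anyDuplicated(disorders))
  target_corr <- as.matrix(target_corr)
  if (!isTRUE(all.equal(dim(target_corr), c(d, d)))) {
    stop_validation("target_corr must be %d x %d", d, d)
  }
  if (max(abs(target_corr - t(target_corr))) > 1e-8) {
    stop_validation("target_corr must be symmetric")
  }
  if (max(abs(diag(target_corr) - 1)) > 1e-8) {
    stop_validation("target_corr must have unit diagonal")
  }
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_validation("target_corr is not positive semidefinite (smallest eigenvalue %.3g)",
                    min(ev))
  }
  means <- rep_len(means, d)
  scales <- rep_len(scales, d)
  if (any(scales <= 0)) stop_validation("scales must be > 0")
  ph <- phenotype_registry(registry)
  for (nm in names(masks)) {
    if (!nm %in% disorders) stop_validation("mask for unknown disorder '%s'", nm)
    bad <- setdiff(masks[[nm]], ph$phenotype)
    if (length(bad)) {
      stop_validation("mask for '%s' names unknown phenotype(s): %s",
                      nm, paste(bad, collapse = ", "))
    }
  }
  # every pair must keep at least 3 shared phenotypes
  present <- lapply(disorders, function(ds) setdiff(ph$phenotype, masks[[ds]]))
  for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
    if (length(intersect(present[[i]], present[[j]])) < 3L) {
      stop_validation("masks leave < 3 shared phenotypes for pair %s",
                      pair_key(disorders[i], disorders[j]))
    }
  }
  structure(list(disorders = disorders, target_corr = target_corr,
                 means = stats::setNames(means, disorders),
                 scales = stats::setNames(scales, disorders),
                 masks = masks, n_table = n_table, seed = as.integer(seed),
                 registry = registry),
            class = "panel_scenario")
}

#' Default panel scenario mimicking the published study design
#'
#' Seven disorders; the target cross-disorder correlation matrix is the
#' published pairwise correlation structure projected to the nearest
#' positive-semidefinite correlation matrix; per-disorder means and
#' scales follow the published profile summaries (e.g. schizophrenia mean
#' d about -0.22, major depression about -0.018); the epilepsy profile
#' lacks all surface-area phenotypes (41 present) and the OCD profile
#' lacks one surface-area phenotype (74 present), reproducing the
#' published pairwise df pattern of 73/72/39.  Sample sizes per measure
#' type come from the packaged ENIGMA working-group table.
#'
#' @param seed integer seed
#' @return a [panel_scenario()]
#' @export
default_panel_scenario <- function(seed = 1L) {
  disorders <- default_disorders()
  pub <- utils::read.delim(system.file("extdata", "published_pairwise.tsv",
                                       package = "neuroconcord", mustWork = TRUE))
  corr <- diag(length(disorders))
  dimnames(corr) <- list(disorders, disorders)
  for (i in seq_len(nrow(pub))) {
    corr[pub$disorder1[i], pub$disorder2[i]] <- pub$r[i]
    corr[pub$disorder2[i], pub$disorder1[i]] <- pub$r[i]
  }
  corr <- nearest_psd_corr(corr)
  ph <- phenotype_registry()
  sa <- ph$phenotype[ph$measure == "surface_area"]
  means <- c(ADHD = -0.05, ASD = -0.04, BD = -0.097, Epilepsy = -0.12,
             MDD = -0.018, OCD = -0.05, SCZ = -0.22)
  scales <- c(ADHD = 0.09, ASD = 0.08, BD = 0.095, Epilepsy = 0.11,
              MDD = 0.05, OCD = 0.08, SCZ = 0.12)
  n_table <- utils::read.delim(system.file("extdata", "enigma_sample_sizes.tsv",
                                           package = "neuroconcord", mustWork = TRUE))
  panel_scenario(disorders, corr,
                 means = means[disorders], scales = scales[disorders],
                 masks = list(Epilepsy = sa, OCD = sa[1]),
                 n_table = n_table, seed = seed)
}

#' Project a symmetric matrix to the nearest positive-semidefinite
#' correlation matrix
#'
#' Eigenvalues are clipped at `eps`, the matrix is reassembled, and the
#' diagonal rescaled to 1.
#'
#' @param m symmetric matrix with unit diagonal
#' @param eps eigenvalue floor (default 1e-8)
#' @return positive-semidefinite correlation matrix
#' @export
nearest_psd_corr <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  out <- e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

#' Generate an effect-size panel from a scenario
#'
#' @param sc a [panel_scenario()]
#' @return a [disorder_panel()]; deterministic given the scenario seed
#' @export
gen_effect_panel <- function(sc) {
  stopifnot(inherits(sc, "panel_scenario"))
  ph <- phenotype_registry(sc$registry)
  n_ph <- nrow(ph)
  d <- length(sc$disorders)
  # eigen-based square root tolerates semidefinite targets (e.g. r = 1)
  e <- eigen(sc$target_corr, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  draws <- with_seed(sc$seed, {
    z <- matrix(stats::rnorm(n_ph * d), n_ph, d)
    z %*% t(L)
  })
  profiles <- lapply(seq_len(d), function(j) {
    ds <- sc$disorders[j]
    vals <- data.frame(region = ph$region, measure = ph$measure,
                       d = sc$means[[ds]] + sc$scales[[ds]] * draws[, j],
                       stringsAsFactors = FALSE)
    drop <- ph$phenotype %in% sc$masks[[ds]]
    vals <- vals[!drop, , drop = FALSE]
    nc <- nk <- NULL
    if (!is.null(sc$n_table)) {
      rows <- sc$n_table[sc$n_table$disorder == ds, ]
      if (nrow(rows)) {
        nc <- stats::setNames(rows$n_cases, rows$measure)
        nk <- stats::setNames(rows$n_controls, rows$measure)
      }
    }
    effect_size_profile(ds, vals, n_cases = nc, n_controls = nk,
                        provenance = "synthetic", registry = sc$registry)
  })
  disorder_panel(profiles, registry = sc$registry)
}

#' GWAS scenario: ground truth for a simulated summary-statistic pair
#'
#' @param m_snps number of SNPs (>= 1000)
#' @param n1,n2 GWAS sample sizes
#' @param h2_1,h2_2 heritabilities in `[0, 1]`
#' @param rg target genetic correlation in `[-1, 1]`
#' @param ld_shape,ld_scale gamma parameters of the LD-score distribution
#'   (scores are `1 + rgamma(shape, scale)`; defaults give mean ~61)
#' @param seed integer seed
#' @return object of class `gwas_scenario`
#' @export
gwas_scenario <- function(m_snps = 20000L, n1 = 50000, n2 = 50000,
                          h2_1 = 0.3, h2_2 = 0.3, rg = 0.68,
                          ld_shape = 1.5, ld_scale = 40, seed = 1L) {
  stopifnot(m_snps >= 1000L, n1 > 0, n2 > 0,
            h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1, abs(rg) <= 1,
            ld_shape > 0, ld_scale > 0)
  structure(list(m_snps = as.integer(m_snps), n1 = n1, n2 = n2,
                 h2_1 = h2_1, h2_2 = h2_2, rg = rg,
                 ld_shape = ld_shape, ld_scale = ld_scale,
                 seed = as.integer(seed)),
            class = "gwas_scenario")
}

#' Generate a pair of GWAS summary-statistic tables with known truth
#'
#' LD scores are drawn from a shifted gamma (minimum 1).  Given its LD
#' score l, SNP j's z statistics are bivariate normal with variances
#' `1 + N_i * h2_i * l / M` and covariance
#' `sqrt(N1 * N2) * rg * sqrt(h2_1 * h2_2) * l / M` - the expectation
#' model that LD-score regression fits.  SNPs are laid out on 22
#' chromosomes at positions clear of the MHC exclusion window, all with
#' INFO = 1, non-ambiguous alleles, and reference MAF drawn uniformly on
#' [0.05, 0.5], so that standard filtering passes everything unless
#' spiked records are requested.
#'
#' @param sc a [gwas_scenario()]
#' @param spike optional named integer vector of deliberately failing
#'   records to append, with any of the names `info` (INFO = 0.5), `mhc`
#'   (inside chr6:25-35 Mb), `missing_ref` (absent from the reference),
#'   `low_ref_maf` (reference MAF 0.01)
#' @param ld optional LD-score table from a previous call, so that
#'   several trait pairs share one LD panel (its row count must equal
#'   `m_snps`); by default a fresh table is drawn
#' @return list with `s1`, `s2` (sumstats), `ld` (LD-score table),
#'   `ref_maf` (named vector)
#' @export
gen_gwas_pair <- function(sc, spike = NULL, ld = NULL) {
  stopifnot(inherits(sc, "gwas_scenario"))
  m <- sc$m_snps
  if (!is.null(ld) && nrow(ld) != m) {
    stop_validation("supplied LD table has %d rows; scenario expects %d",
                    nrow(ld), m)
  }
  with_seed(sc$seed, {
    l2 <- if (is.null(ld)) {
      1 + stats::rgamma(m, shape = sc$ld_shape, scale = sc$ld_scale)
    } else ld$l2
    v1 <- 1 + sc$n1 * sc$h2_1 * l2 / m
    v2 <- 1 + sc$n2 * sc$h2_2 * l2 / m
    cv <- sqrt(sc$n1 * sc$n2 * sc$h2_1 * sc$h2_2) * sc$rg * l2 / m
    if (any(v1 * v2 - cv^2 < 0)) {
      stop_validation("per-SNP covariance matrix not positive semidefinite")
    }
    u1 <- stats::rnorm(m)
    u2 <- stats::rnorm(m)
    z1 <- sqrt(v1) * u1
    z2 <- cv / sqrt(v1) * u1 + sqrt(pmax(v2 - cv^2 / v1, 0)) * u2
    chr <- rep(seq_len(22L), length.out = m)
    bp <- 40e6 + 1000 * (seq_len(m) - 1) %/% 22  # clear of the 25-35 Mb window
    snp <- sprintf("rs%07d", seq_len(m))
    alleles <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), 4, 2, byrow = TRUE)
    pick <- sample.int(4L, m, replace = TRUE)
    base <- function(z, n) {
      validate_sumstats(data.frame(
        snp = snp, chr = chr, bp = bp,
        a1 = alleles[pick, 1], a2 = alleles[pick, 2],
        z = z, n = n, info = 1,
        stringsAsFactors = FALSE))
    }
    s1 <- base(z1, sc$n1)
    s2 <- base(z2, sc$n2)
    ld <- data.frame(chr = chr, snp = snp, bp = bp, l2 = l2,
                     stringsAsFactors = FALSE)
    ref <- stats::setNames(stats::runif(m, 0.05, 0.5), snp)
    if (!is.null(spike)) {
      sp <- spike_records(spike)
      s1 <- validate_sumstats(rbind(as.data.frame(s1), sp$records))
      s2 <- validate_sumstats(rbind(as.data.frame(s2), sp$records))
      ref <- c(ref, sp$ref)
    }
    list(s1 = s1, s2 = s2, ld = ld, ref_maf = ref)
  })
}

# records engineered to fail one filter rule each
spike_records <- function(spike) {
  spike <- spike[spike > 0]
  recs <- list(); ref <- numeric(0)
  mk <- function(n, tag, chr, bp, info) {
    data.frame(snp = sprintf("spike_%s_%03d", tag, seq_len(n)),
               chr = chr, bp = bp, a1 = "A", a2 = "G",
               z = 0, n = 10000, info = info, stringsAsFactors = FALSE)
  }
  if (!is.na(spike["info"])) {
    r <- mk(spike[["info"]], "info", 1L, 50e6, 0.5)
    recs <- c(recs, list(r)); ref <- c(ref, stats::setNames(rep(0.25, nrow(r)), r$snp))
  }
  if (!is.na(spike["mhc"])) {
    r <- mk(spike[["mhc"]], "mhc", 6L, 30e6, 1)
    recs <- c(recs, list(r)); ref <- c(ref, stats::setNames(rep(0.25, nrow(r)), r$snp))
  }
  if (!is.na(spike["missing_ref"])) {
    r <- mk(spike[["missing_ref"]], "missing", 2L, 50e6, 1)
    recs <- c(recs, list(r))  # no reference entries on purpose
  }
  if (!is.na(spike["low_ref_maf"])) {
    r <- mk(spike[["low_ref_maf"]], "lowmaf", 3L, 50e6, 1)
    recs <- c(recs, list(r)); ref <- c(ref, stats::setNames(rep(0.01, nrow(r)), r$snp))
  }
  list(records = do.call(rbind, recs), ref = ref)
}

#' Plausible cross-disorder genetic correlations for the default design
#'
#' A synthetic 21-pair rg vector on the scale reported in large
#' cross-disorder GWAS analyses (high for schizophrenia-bipolar, near
#' zero for epilepsy with psychiatric disorders).  Used as the default
#' input to [gen_joint_scenario()]; not estimated from data.
#'
#' @return named numeric vector keyed by [pair_key()]
#' @export
default_rg_vector <- function() {
  v <- c("BD|SCZ" = 0.70, "MDD|SCZ" = 0.34, "OCD|SCZ" = 0.33,
         "ASD|SCZ" = 0.21, "ADHD|SCZ" = 0.12, "Epilepsy|SCZ" = 0.10,
         "BD|MDD" = 0.36, "BD|OCD" = 0.31, "ADHD|BD" = 0.09,
         "ASD|BD" = 0.18, "BD|Epilepsy" = 0.08, "ADHD|MDD" = 0.42,
         "MDD|OCD" = 0.28, "ASD|MDD" = 0.31, "Epilepsy|MDD" = 0.05,
         "ADHD|OCD" = -0.17, "ASD|OCD" = 0.22, "Epilepsy|OCD" = 0.02,
         "ADHD|ASD" = 0.36, "ADHD|Epilepsy" = 0.04, "ASD|Epilepsy" = 0.03)
  v[order(names(v))]
}

#' Joint scenario: couple the imaging correlation structure to a genetic
#' correlation vector at a target rank correlation
#'
#' Builds a panel scenario whose off-diagonal target correlations are a
#' monotone map of the supplied rg values plus calibrated rank noise, so
#' that the expected Spearman correlation between the pairwise imaging
#' correlations and rg equals `coupling`.  The construction works on
#' normal scores: the latent vector is `a * z(rg) + sqrt(1 - a^2) * eps`
#' with `a = 2 * sin(pi * coupling / 6)` (the Pearson correlation of a
#' bivariate normal whose Spearman correlation is `coupling`), then maps
#' monotonically to the correlation scale via `tanh` and projects to the
#' nearest positive-semidefinite correlation matrix.  The achieved
#' (post-projection, pre-sampling) coupling is reported alongside the
#' request.
#'
#' @param rg_vector named rg values keyed by [pair_key()] over all pairs
#'   of D disorders (default [default_rg_vector()])
#' @param coupling target Spearman correlation in `[-1, 1]`; at
#'   `|coupling| = 1` no rank noise is added
#' @param seed integer seed (drives both the rank noise and the panel
#'   scenario)
#' @param base scenario supplying disorders, means, scales, masks and
#'   sample sizes (default [default_panel_scenario()])
#' @param spread_mu,spread_sd location and spread of the constructed
#'   correlations on the atanh scale (defaults give off-diagonals roughly
#'   in -0.5..0.8, the published range)
#' @return list of class `joint_scenario`: `scenario` (a
#'   [panel_scenario()]), `rg` (the input vector), `requested_coupling`,
#'   `achieved_coupling`
#' @export
gen_joint_scenario <- function(rg_vector = default_rg_vector(), coupling = 0.44,
                               seed = 1L, base = default_panel_scenario(),
                               spread_mu = 0.15, spread_sd = 0.35) {
  stopifnot(abs(coupling) <= 1)
  disorders <- base$disorders
  d <- length(disorders)
  keys <- utils::combn(disorders, 2L, function(p) pair_key(p[1], p[2]))
  if (!setequal(names(rg_vector), keys)) {
    stop_validation("rg_vector must cover exactly the %d pairs of {%s}; missing: {%s}, extra: {%s}",
                    length(keys), paste(disorders, collapse = ", "),
                    paste(setdiff(keys, names(rg_vector)), collapse = ", "),
                    paste(setdiff(names(rg_vector), keys), collapse = ", "))
  }
  rg_vector <- rg_vector[keys]
  p <- length(keys)
  zscore <- stats::qnorm((rank(rg_vector, ties.method = "average") - 0.5) / p)
  a <- 2 * sin(pi * coupling / 6)
  u <- if (abs(coupling) == 1) {
    sign(coupling) * zscore
  } else {
    with_seed(derive_seed(seed, "joint-noise"),
              a * zscore + sqrt(1 - a^2) * stats::rnorm(p))
  }
  u_std <- (u - mean(u)) / stats::sd(u)
  t_off <- tanh(spread_mu + spread_sd * u_std)
  corr <- diag(d)
  dimnames(corr) <- list(disorders, disorders)
  idx <- utils::combn(d, 2L)
  for (j in seq_len(p)) {
    corr[idx[1, j], idx[2, j]] <- corr[idx[2, j], idx[1, j]] <- t_off[j]
  }
  proj <- nearest_psd_corr(corr)
  achieved <- stats::cor(proj[t(idx)], rg_vector, method = "spearman")
  sc <- panel_scenario(disorders, proj, means = base$means,
                       scales = base$scales, masks = base$masks,
                       n_table = base$n_table, seed = derive_seed(seed, "panel"),
                       registry = base$registry)
  structure(list(scenario = sc, rg = rg_vector,
                 requested_coupling = coupling, achieved_coupling = achieved),
            class = "joint_scenario")
}
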