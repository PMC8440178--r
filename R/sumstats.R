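# GWAS summary-statistic I/O and pre-regression filtering

SUMSTATS_ALIASES <- list(
  snp  = c("snp", "markername", "rsid", "snpid", "rs"),
  chr  = c("chr", "chromosome"),
  bp   = c("bp", "pos", "position", "bpos"),
  a1   = c("a1", "allele1", "effect_allele"),
  a2   = c("a2", "allele2", "other_allele"),
  z    = c("z", "zscore", "z_score"),
  beta = c("beta", "b", "effect"),
  se   = c("se", "stderr", "standard_error"),
  or   = c("or", "odds_ratio"),
  n    = c("n", "ntot", "n_total", "neff"),
  info = c("info", "imputation_quality"),
  maf  = c("maf", "frq", "freq", "eaf")
)

#' Read GWAS summary statistics
#'
#' Accepts whitespace- or tab-delimited files with the usual munged
#' layout: columns SNP, CHR, BP, A1, A2 plus an association statistic as
#' either Z, BETA+SE, or OR+SE (converted to `z = beta/se` or
#' `z = log(OR)/se`), sample size N, and optional INFO and MAF.  Header
#' names are case-insensitive and common aliases are recognized.
#' Allele frequencies above 0.5 are folded to minor-allele frequencies.
#'
#' @param path file path
#' @param n sample size to use when the file has no N column
#' @return data frame of class `sumstats` with columns `snp`, `chr`, `bp`,
#'   `a1`, `a2`, `z`, `n`, and `info`/`maf` when available
#' @export
read_sumstats <- function(path, n = NULL) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  names(raw) <- tolower(names(raw))
  pick <- function(key) {
    hit <- intersect(SUMSTATS_ALIASES[[key]], names(raw))
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  out <- data.frame(snp = as.character(pick("snp")), stringsAsFactors = FALSE)
  if (!nrow(out) || is.null(pick("snp"))) {
    stop_validation("no SNP id column found in '%s'", path)
  }
  out$chr <- as.integer(gsub("^chr", "", as.character(pick("chr") %||% NA)))
  out$bp <- as.integer(pick("bp") %||% NA)
  out$a1 <- toupper(as.character(pick("a1") %||% NA))
  out$a2 <- toupper(as.character(pick("a2") %||% NA))
  z <- pick("z")
  if (is.null(z)) {
    se <- pick("se")
    if (!is.null(pick("beta")) && !is.null(se)) {
      z <- pick("beta") / se
    } else if (!is.null(pick("or")) && !is.null(se)) {
      z <- log(pick("or")) / se
    } else {
      stop_validation("no Z, BETA+SE or OR+SE columns found in '%s'", path)
    }
  }
  out$z <- as.numeric(z)
  out$n <- as.numeric(pick("n") %||% n)
  if (all(is.na(out$n))) stop_validation("no sample size column; supply n =")
  info <- pick("info")
  if (!is.null(info)) out$info <- as.numeric(info)
  maf <- pick("maf")
  if (!is.null(maf)) {
    maf <- as.numeric(maf)
    out$maf <- pmin(maf, 1 - maf)
  }
  validate_sumstats(out, path)
}

validate_sumstats <- function(out, label = "sumstats") {
  if (anyDuplicated(out$snp)) {
    stop_validation("duplicate SNP id(s) in %s: %s", label,
                    paste(utils::head(unique(out$snp[duplicated(out$snp)]), 3),
                          collapse = ", "))
  }
  if (any(!is.finite(out$z))) stop_validation("non-finite z statistics in %s", label)
  if (any(out$n <= 0, na.rm = TRUE)) stop_validation("non-positive N in %s", label)
  if (!is.null(out$info) && any(out$info < 0, na.rm = TRUE)) {
    stop_validation("negative INFO in %s", label)
  }
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Read an LD-score table
#'
#' Tab-delimited with columns CHR, SNP, BP, L2 (case-insensitive).
#'
#' @param path file path
#' @return data frame with columns `snp`, `chr`, `bp`, `l2`
#' @export
read_ldscores <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("chr", "snp", "bp", "l2")
  if (!all(need %in% names(raw))) {
    stop_validation("LD-score file must have columns CHR, SNP, BP, L2")
  }
  out <- raw[, need]
  if (any(out$l2 <= 0)) stop_validation("LD scores must be > 0")
  if (anyDuplicated(out$snp)) stop_validation("duplicate SNP ids in LD-score table")
  out
}

#' Read a reference-panel MAF table
#'
#' Tab-delimited with columns SNP, MAF.
#'
#' @param path file path
#' @return named numeric vector of MAF keyed by SNP id
#' @export
read_ref_maf <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("snp", "maf") %in% names(raw))) {
    stop_validation("reference MAF file must have columns SNP, MAF")
  }
  stats::setNames(pmin(raw$maf, 1 - raw$maf), raw$snp)
}

#' Filter summary statistics before LD-score regression
#'
#' Applies the conventional pre-regression filters: drops markers with
#' imputation INFO below `info_min` (records lacking INFO are kept and
#' counted), drops markers inside the MHC region (hg19 chr6:25-35 Mb,
#' bounds inclusive), and retains only markers present in the reference
#' panel with reference MAF of at least `maf_min`.
#'
#' @param s a `sumstats` table
#' @param ref_maf named numeric vector of reference-panel MAF keyed by SNP
#'   id (see [read_ref_maf()])
#' @param info_min INFO threshold (default 0.90)
#' @param maf_min reference MAF threshold (default 0.05)
#' @param mhc_chr,mhc_range MHC coordinates (default chr6, 25-35 Mb, hg19)
#' @return filtered `sumstats` table; attribute `filter_log` is a named
#'   integer vector of drop counts per rule (`info`, `mhc`,
#'   `not_in_reference`, `low_ref_maf`, plus `kept` and `no_info_kept`)
#' @export
filter_sumstats <- function(s, ref_maf, info_min = 0.90, maf_min = 0.05,
                            mhc_chr = 6L, mhc_range = c(25e6, 35e6)) {
  stopifnot(inherits(s, "data.frame"))
  if (length(ref_maf) == 0L) stop_validation("reference MAF mapping is empty")
  log <- c(info = 0L, mhc = 0L, not_in_reference = 0L, low_ref_maf = 0L,
           kept = 0L, no_info_kept = 0L)
  if (!is.null(s$info)) {
    has_info <- !is.na(s$info)
    drop <- has_info & s$info < info_min
    log["info"] <- sum(drop)
    log["no_info_kept"] <- sum(!has_info)
    s <- s[!drop, , drop = FALSE]
  } else {
    log["no_info_kept"] <- nrow(s)
  }
  in_mhc <- !is.na(s$chr) & !is.na(s$bp) & s$chr == mhc_chr &
    s$bp >= mhc_range[1] & s$bp <= mhc_range[2]
  log["mhc"] <- sum(in_mhc)
  s <- s[!in_mhc, , drop = FALSE]
  present <- s$snp %in% names(ref_maf)
  log["not_in_reference"] <- sum(!present)
  s <- s[present, , drop = FALSE]
  low <- ref_maf[s$snp] < maf_min
  log["low_ref_maf"] <- sum(low)
  s <- s[!low, , drop = FALSE]
  log["kept"] <- nrow(s)
  if (nrow(s) == 0L) {
    stop_validation("no markers survive filtering (dropped: %s)",
                    paste(sprintf("%s=%d", names(log), log), collapse = ", "))
  }
  attr(s, "filter_log") <- log
  s
}

#' Read a precomputed genetic-correlation table
#'
#' TSV with columns `disorder1`, `disorder2`, `rg`, `se`; an alternative
#' to running LD-score regression when published genetic correlations are
#' available.
#'
#' @param path file path
#' @return data frame with columns `disorder1`, `disorder2`, `pair`, `rg`,
#'   `se`
#' @export
read_rg_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("disorder1", "disorder2", "rg", "se")
  if (!all(need %in% names(raw))) {
    stop_validation("rg table must have columns %s", paste(need, collapse = ", "))
  }
  raw$pair <- pair_key(raw$disorder1, raw$disorder2)
  if (anyDuplicated(raw$pair)) {
    stop_validation("duplicate pair(s) in rg table: %s",
                    paste(unique(raw$pair[duplicated(raw$pair)]), collapse = ", "))
  }
  if (any(abs(raw$rg) > 1.25)) {
    stop_validation("|rg| > 1.25 in rg table (row %d)", which(abs(raw$rg) > 1.25)[1])
  }
  if (any(raw$se <= 0)) stop_validation("rg standard errors must be > 0")
  raw[, c("disorder1", "disorder2", "pair", "rg", "se")]
}
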