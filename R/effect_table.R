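#' Construct an effect-size profile for one disorder
#'
#' An effect-size profile holds one disorder's case-control Cohen's d
#' (standardized mean difference, case minus control, covariate-adjusted)
#' for each measured brain phenotype, together with the per-measure-type
#' case and control counts when known.  Missing phenotypes are simply
#' absent rows; e.g. a disorder with no surface-area measures has 41 of
#' the 75 default phenotypes.
#'
#' @param disorder disorder label (character scalar)
#' @param values data frame with columns `region`, `measure`, `d`
#' @param n_cases,n_controls optional named numeric vectors of participant
#'   counts, named by measure type (`thickness`, `surface_area`,
#'   `subcortical_volume`)
#' @param provenance free-text source label
#' @param registry phenotype registry, see [brain_registry()]
#' @return object of class `effect_size_profile`
#' @export
effect_size_profile <- function(disorder, values, n_cases = NULL,
                                n_controls = NULL, provenance = "",
                                registry = brain_registry()) {
  stopifnot(is.character(disorder), length(disorder) == 1L, nzchar(disorder))
  if (!is.data.frame(values) || !all(c("region", "measure", "d") %in% names(values))) {
    stop_validation("profile values need columns region, measure, d")
  }
  values$region <- canonical_region(values$region)
  msgs <- check_phenotype(values$region, values$measure, registry)
  if (length(msgs)) {
    stop_validation("invalid phenotypes for disorder '%s': %s",
                    disorder, paste(unique(msgs), collapse = "; "))
  }
  values$phenotype <- paste(values$region, values$measure, sep = ":")
  if (anyDuplicated(values$phenotype)) {
    dup <- values$phenotype[duplicated(values$phenotype)]
    stop_validation("duplicate phenotype(s) for disorder '%s': %s",
                    disorder, paste(unique(dup), collapse = ", "))
  }
  d <- as.numeric(values$d)
  if (any(!is.finite(d))) {
    stop_validation("non-finite Cohen's d for disorder '%s'", disorder)
  }
  if (any(abs(d) >= 5)) {
    stop_validation("implausible |d| >= 5 for disorder '%s' (max %.3g)",
                    disorder, max(abs(d)))
  }
  for (nv in list(n_cases, n_controls)) {
    if (!is.null(nv)) {
      if (is.null(names(nv)) || !all(names(nv) %in% MEASURES)) {
        stop_validation("participant counts must be named by measure type")
      }
      if (any(!is.na(nv) & nv < 2)) {
        stop_validation("participant counts must be >= 2 (disorder '%s')", disorder)
      }
    }
  }
  # order rows by the registry's fixed phenotype order
  ord <- phenotype_registry(registry)$phenotype
  values <- values[order(match(values$phenotype, ord)), , drop = FALSE]
  values$d <- as.numeric(values$d)
  rownames(values) <- NULL
  structure(
    list(disorder = disorder,
         values = values[, c("region", "measure", "phenotype", "d")],
         n_cases = n_cases, n_controls = n_controls,
         provenance = provenance),
    class = "effect_size_profile"
  )
}

#' @export
print.effect_size_profile <- function(x, ...) {
  cat(sprintf("<effect_size_profile> %s: %d phenotypes, mean d = %.3f\n",
              x$disorder, nrow(x$values), mean(x$values$d)))
  invisible(x)
}

#' Bundle effect-size profiles into a disorder panel
#'
#' @param profiles list of [effect_size_profile()] objects (>= 2, unique
#'   disorder labels); the list order fixes the disorder order
#' @param registry shared phenotype registry
#' @return object of class `disorder_panel`
#' @export
disorder_panel <- function(profiles, registry = brain_registry()) {
  stopifnot(is.list(profiles))
  if (length(profiles) < 2L) {
    stop_validation("a disorder panel needs at least 2 profiles")
  }
  ok <- vapply(profiles, inherits, logical(1), "effect_size_profile")
  if (!all(ok)) stop_validation("all panel elements must be effect_size_profile objects")
  labs <- vapply(profiles, `[[`, character(1), "disorder")
  if (anyDuplicated(labs)) {
    stop_validation("duplicate disorder labels: %s",
                    paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  names(profiles) <- labs
  structure(list(profiles = profiles, registry = registry),
            class = "disorder_panel")
}

#' @export
print.disorder_panel <- function(x, ...) {
  d <- length(x$profiles)
  cat(sprintf("<disorder_panel> %d disorders (%d pairs): %s\n",
              d, d * (d - 1) / 2, paste(names(x$profiles), collapse = ", ")))
  invisible(x)
}

#' Disorder labels of a panel
#' @param panel a `disorder_panel`
#' @return character vector
#' @export
panel_disorders <- function(panel) names(panel$profiles)

#' Read a disorder panel from a tab-separated effect table
#'
#' The file must be UTF-8 TSV with header columns `disorder`, `region`,
#' `measure`, `d` and optional `n_cases`, `n_controls` (counts constant
#' within a disorder and measure type; empty fields allowed).  Unknown
#' (region, measure) combinations, duplicate rows and non-numeric d are
#' rejected with the offending line number.
#'
#' @param path file path
#' @param registry phenotype registry
#' @return a [disorder_panel()]
#' @export
read_effect_table <- function(path, registry = brain_registry()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  need <- c("disorder", "region", "measure", "d")
  if (!all(need %in% names(raw))) {
    stop_validation("effect table must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop_validation("effect table '%s' is empty", path)
  dnum <- suppressWarnings(as.numeric(raw$d))
  bad <- which(is.na(dnum))
  if (length(bad)) {
    stop_validation("non-numeric d at line %d of '%s'", bad[1] + 1L, path)
  }
  raw$d <- dnum
  for (col in c("n_cases", "n_controls")) {
    if (col %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      mal <- which(is.na(v) & !is.na(raw[[col]]))
      if (length(mal)) {
        stop_validation("non-numeric %s at line %d of '%s'", col, mal[1] + 1L, path)
      }
      raw[[col]] <- v
    } else {
      raw[[col]] <- NA_real_
    }
  }
  profiles <- lapply(split(raw, factor(raw$disorder, levels = unique(raw$disorder))),
                     function(rows) {
    nc <- measure_counts(rows, "n_cases")
    nk <- measure_counts(rows, "n_controls")
    effect_size_profile(rows$disorder[1],
                        rows[, c("region", "measure", "d")],
                        n_cases = nc, n_controls = nk,
                        provenance = path, registry = registry)
  })
  disorder_panel(unname(profiles), registry = registry)
}

# collapse per-row counts to one count per measure type; NULL when all absent
measure_counts <- function(rows, col) {
  v <- rows[[col]]
  if (all(is.na(v))) return(NULL)
  out <- vapply(split(v, rows$measure), function(x) {
    u <- unique(x[!is.na(x)])
    if (length(u) == 0L) return(NA_real_)
    if (length(u) > 1L) {
      stop_validation("inconsistent %s within disorder '%s', measure '%s'",
                      col, rows$disorder[1], rows$measure[match(x[1], v)])
    }
    u
  }, numeric(1))
  out[!is.na(out)]
}

#' Write a disorder panel to a tab-separated effect table
#'
#' d values are written at full precision (`%.17g`) so that
#' read/write round-trips are bit-identical.
#'
#' @param panel a `disorder_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_effect_table <- function(panel, path) {
  rows <- lapply(panel$profiles, function(p) {
    v <- p$values
    data.frame(disorder = p$disorder, region = v$region, measure = v$measure,
               d = sprintf("%.17g", v$d),
               n_cases = count_for(p$n_cases, v$measure),
               n_controls = count_for(p$n_controls, v$measure),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

count_for <- function(nv, measure) {
  if (is.null(nv)) return(rep(NA_real_, length(measure)))
  unname(nv[measure])
}

#' Paired effect sizes over the shared phenotypes of two profiles
#'
#' Returns the ordered pairs (d_a, d_b) over phenotypes present in both
#' profiles, in registry order.  The number of shared phenotypes minus 2
#' is the degrees of freedom of the pairwise correlation: 75 shared
#' phenotypes give df = 73, 74 give 72, and a thickness+subcortical-only
#' profile against a complete one gives 41 shared phenotypes, df = 39.
#'
#' @param a,b `effect_size_profile` objects
#' @return data frame with columns `region`, `measure`, `phenotype`,
#'   `d_a`, `d_b`; attribute `n_overlap`
#' @export
intersect_phenotypes <- function(a, b) {
  stopifnot(inherits(a, "effect_size_profile"), inherits(b, "effect_size_profile"))
  common <- intersect(a$values$phenotype, b$values$phenotype)
  if (length(common) < 3L) {
    stop_validation("profiles '%s' and '%s' share only %d phenotype(s); need >= 3 for a correlation",
                    a$disorder, b$disorder, length(common))
  }
  ia <- a$values[match(common, a$values$phenotype), ]
  ib <- b$values[match(common, b$values$phenotype), ]
  out <- data.frame(region = ia$region, measure = ia$measure,
                    phenotype = common, d_a = ia$d, d_b = ib$d,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_overlap") <- nrow(out)
  out
}
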