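# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered pair key
#'
#' Disorder pairs are identified by a canonical key `"A|B"` with the two
#' labels in lexicographic order, so that `pair_key("SCZ", "BD")` and
#' `pair_key("BD", "SCZ")` name the same pair.
#'
#' @param a,b disorder labels (character scalars or vectors of equal length)
#' @return character vector of pair keys
#' @export
#' @examples
#' pair_key("SCZ", "BD")
pair_key <- function(a, b) {
  stopifnot(length(a) == length(b))
  mapply(function(x, y) paste(sort(c(x, y)), collapse = "|"),
         as.character(a), as.character(b), USE.NAMES = FALSE)
}

# Deterministic 31-bit seed derived from a master seed and a string label.
# Used to give every disorder pair its own reproducible permutation stream
# independent of the order in which pairs are evaluated.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- as.numeric(master) %% 2147483647
  for (k in utf8ToInt(paste0("|", label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# format p values the way the pairwise output table prints them:
# 3 significant digits, scientific when small
format_pval <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    format(signif(x, 3), scientific = x < 1e-3, trim = TRUE)
  }, character(1))
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
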