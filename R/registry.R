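#' Brain phenotype registry
#'
#' The default registry covers the 34 Desikan-Killiany cortical parcels and
#' 7 subcortical structures (41 regions) used by the ENIGMA disorder working
#' groups, with left/right hemispheres already averaged.  Each cortical
#' region contributes two phenotypes (cortical thickness and surface area)
#' and each subcortical region one (volume), for 75 phenotypes in total.
#'
#' @param path optional path to a custom registry TSV with columns
#'   `region` and `class` (`cortical` or `subcortical`); defaults to the
#'   packaged Desikan-Killiany + subcortical registry.
#' @return data frame with columns `region` and `class`
#' @export
#' @examples
#' reg <- brain_registry()
#' table(reg$class)
brain_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk_registry.tsv", package = "neuroconcord",
                        mustWork = TRUE)
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region", "class") %in% names(reg))) {
    stop_validation("registry file must have columns 'region' and 'class'")
  }
  reg$region <- canonical_region(reg$region)
  bad <- setdiff(unique(reg$class), c("cortical", "subcortical"))
  if (length(bad)) {
    stop_validation("unknown region class(es): %s", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(reg$region)) {
    stop_validation("duplicate region names in registry")
  }
  reg
}

#' Canonicalize region names
#'
#' Lower-cases and replaces whitespace/hyphens with underscores so that
#' e.g. "Superior Frontal" and "superior_frontal" match.
#'
#' @param x character vector of region names
#' @return canonical names
#' @export
canonical_region <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

#' Valid measures
#' @keywords internal
MEASURES <- c("thickness", "surface_area", "subcortical_volume")

#' Enumerate all phenotypes of a registry
#'
#' A phenotype is a (region, measure) pair: thickness and surface area for
#' each cortical region, volume for each subcortical region.  Rows are in
#' registry order, with the two cortical measures interleaved per region;
#' this fixed order defines the alignment used by all pairwise operations.
#'
#' @param registry a registry data frame from [brain_registry()]
#' @return data frame with columns `region`, `measure`, and `phenotype`
#'   (the `"region:measure"` id)
#' @export
#' @examples
#' nrow(phenotype_registry())  # 75 for the default registry
phenotype_registry <- function(registry = brain_registry()) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    if (registry$class[i] == "cortical") {
      data.frame(region = registry$region[i],
                 measure = c("thickness", "surface_area"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(region = registry$region[i],
                 measure = "subcortical_volume",
                 stringsAsFactors = FALSE)
    }
  })
  ph <- do.call(rbind, rows)
  ph$phenotype <- paste(ph$region, ph$measure, sep = ":")
  ph
}

# validate a (region, measure) combination against the registry;
# returns a character vector of error messages (empty when valid)
check_phenotype <- function(region, measure, registry) {
  msgs <- character(0)
  cls <- registry$class[match(region, registry$region)]
  unknown <- is.na(cls)
  if (any(unknown)) {
    msgs <- c(msgs, sprintf("unknown region '%s'", unique(region[unknown])))
  }
  badm <- !measure %in% MEASURES
  if (any(badm)) {
    msgs <- c(msgs, sprintf("unknown measure '%s'", unique(measure[badm])))
  }
  ok <- !unknown & !badm
  mismatch <- ok & ((cls == "subcortical" & measure != "subcortical_volume") |
                    (cls == "cortical" & measure == "subcortical_volume"))
  if (any(mismatch)) {
    msgs <- c(msgs, sprintf("measure '%s' invalid for %s region '%s'",
                            measure[mismatch], cls[mismatch], region[mismatch]))
  }
  msgs
}
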