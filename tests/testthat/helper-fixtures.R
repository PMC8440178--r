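# fixtures built in code; no binary files

# deterministic complete profile over all 75 phenotypes
make_profile <- function(disorder, offset = 0, mask = NULL,
                         n_cases = NULL, n_controls = NULL) {
  ph <- phenotype_registry()
  d <- round(sin(seq_len(nrow(ph)) + offset) / 10, 6)
  vals <- data.frame(region = ph$region, measure = ph$measure, d = d,
                     stringsAsFactors = FALSE)
  if (!is.null(mask)) vals <- vals[!ph$phenotype %in% mask, ]
  effect_size_profile(disorder, vals, n_cases = n_cases,
                      n_controls = n_controls)
}

# panel with the published overlap pattern: two complete profiles, one
# missing a single surface-area phenotype, one missing all surface area
make_masked_panel <- function() {
  ph <- phenotype_registry()
  sa <- ph$phenotype[ph$measure == "surface_area"]
  disorder_panel(list(
    make_profile("A", 0),
    make_profile("B", 1),
    make_profile("C", 2, mask = sa[1]),
    make_profile("D", 3, mask = sa)
  ))
}

published_pairwise <- function() {
  utils::read.delim(system.file("extdata", "published_pairwise.tsv",
                                package = "neuroconcord", mustWork = TRUE))
}

# ten-SNP sumstats fixture for the filter contract: 2 fail INFO, 1 in the
# MHC, 2 absent from the reference, 1 below reference MAF; 4 survive
make_filter_fixture <- function() {
  s <- data.frame(
    snp = sprintf("rs%d", 1:10),
    chr = c(1, 1, 6, 2, 2, 3, 3, 4, 4, 5),
    bp  = c(1e6, 2e6, 30e6, 1e6, 2e6, 1e6, 2e6, 1e6, 2e6, 1e6),
    a1 = "A", a2 = "G",
    z = rnorm(10), n = 1e4,
    info = c(0.85, 0.85, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  # rs4, rs5 absent from reference; rs6 below the reference MAF threshold
  ref <- setNames(rep(0.25, 7), c("rs1", "rs2", "rs3", "rs6", "rs8", "rs9", "rs10"))
  ref["rs6"] <- 0.01
  ref["rs7"] <- 0.30
  list(s = neuroconcord:::validate_sumstats(s), ref = ref)
}

# small gwas pair for fast LDSC unit tests
small_gwas <- function(seed = 1, rg = 0.5, h2_1 = 0.4, h2_2 = 0.4,
                       m = 4000, n = 50000, ld = NULL) {
  gen_gwas_pair(gwas_scenario(m_snps = m, n1 = n, n2 = n, h2_1 = h2_1,
                              h2_2 = h2_2, rg = rg, seed = seed), ld = ld)
}
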