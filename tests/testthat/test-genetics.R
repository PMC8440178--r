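test_that("sumstats filtering drops exactly the engineered records", {
  fx <- make_filter_fixture()
  out <- filter_sumstats(fx$s, fx$ref)
  expect_equal(nrow(out), 4)
  expect_setequal(out$snp, c("rs7", "rs8", "rs9", "rs10"))
  log <- attr(out, "filter_log")
  expect_equal(unname(log[c("info", "mhc", "not_in_reference", "low_ref_maf")]),
               c(2L, 1L, 2L, 1L))
  expect_equal(unname(log["kept"]), 4L)
})

test_that("the MHC exclusion window is inclusive at both bounds", {
  s <- neuroconcord:::validate_sumstats(data.frame(
    snp = c("a", "b", "c", "d"), chr = 6L,
    bp = c(24999999, 25000000, 35000000, 35000001),
    a1 = "A", a2 = "G", z = 0.5, n = 1e4, info = 1,
    stringsAsFactors = FALSE))
  ref <- setNames(rep(0.3, 4), s$snp)
  out <- filter_sumstats(s, ref)
  expect_setequal(out$snp, c("a", "d"))
})

test_that("clean tables pass filtering unchanged; INFO-free records are kept", {
  fx <- make_filter_fixture()
  clean <- fx$s[fx$s$snp %in% c("rs8", "rs9", "rs10"), ]
  out <- filter_sumstats(clean, fx$ref)
  expect_equal(out$snp, clean$snp)
  noinfo <- clean
  noinfo$info <- NULL
  out2 <- filter_sumstats(noinfo, fx$ref)
  expect_equal(nrow(out2), 3)
  expect_equal(unname(attr(out2, "filter_log")["no_info_kept"]), 3L)
  expect_error(filter_sumstats(clean, fx$ref["rs1"]), "no markers survive")
})

test_that("sumstats readers normalise aliases and convert effect columns", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MarkerName CHR POS Allele1 Allele2 BETA SE N INFO FRQ",
               "rs1 1 1000 a g 0.10 0.05 5000 0.99 0.60",
               "rs2 2 2000 t c -0.20 0.04 5000 0.95 0.10"), path)
  s <- read_sumstats(path)
  expect_equal(s$z, c(0.10 / 0.05, -0.20 / 0.04))
  expect_equal(s$a1, c("A", "T"))
  expect_equal(s$maf, c(0.40, 0.10))   # folded to minor allele

  writeLines(c("SNP CHR BP A1 A2 OR SE N",
               "rs1 1 1000 A G 1.2 0.1 8000"), path)
  s2 <- read_sumstats(path)
  expect_equal(s2$z, log(1.2) / 0.1)

  writeLines(c("SNP CHR BP A1 A2 Z N",
               "rs1 1 1000 A G 1.0 8000",
               "rs1 1 1001 A G 2.0 8000"), path)
  expect_error(read_sumstats(path), "duplicate")
})

test_that("LDSC on null simulations recovers zero h2 and unit intercept", {
  g <- small_gwas(seed = 21, h2_1 = 0, h2_2 = 0, rg = 0, m = 4000)
  fit <- ldsc_h2(g$s1, g$ld, n_blocks = 50)
  expect_lt(abs(fit$h2 - 0), 3 * fit$h2_se)
  expect_lt(abs(fit$intercept - 1), 3 * fit$intercept_se)
})

test_that("LDSC recovers a simulated heritability within jackknife error", {
  g <- small_gwas(seed = 31, h2_1 = 0.4, h2_2 = 0.4, rg = 0, m = 8000)
  fit <- ldsc_h2(g$s1, g$ld, n_blocks = 100)
  expect_lt(abs(fit$h2 - 0.4), 3 * fit$h2_se)
  expect_equal(fit$m_snps, 8000)
})

test_that("constant LD scores make the regression fail loudly", {
  g <- small_gwas(seed = 5, m = 1000)
  g$ld$l2 <- 5
  expect_error(ldsc_h2(g$s1, g$ld, n_blocks = 10), "no variation")
})

test_that("self-correlation gives rg 1; estimator is symmetric in its inputs", {
  g <- small_gwas(seed = 41, h2_1 = 0.3, h2_2 = 0.3, rg = 0.4, m = 6000)
  self <- ldsc_rg(g$s1, g$s1, g$ld, n_blocks = 50)
  expect_equal(self$rg, 1, tolerance = 1e-10)
  ab <- ldsc_rg(g$s1, g$s2, g$ld, n_blocks = 50)
  ba <- ldsc_rg(g$s2, g$s1, g$ld, n_blocks = 50)
  expect_equal(ab$rg, ba$rg, tolerance = 1e-12)
  expect_equal(ab$se_rg, ba$se_rg, tolerance = 1e-12)
  expect_lt(abs(ab$rg - 0.4), 3 * ab$se_rg)
})

test_that("allele orientation is reconciled before the bivariate fit", {
  g <- small_gwas(seed = 51, rg = 0.5, m = 4000)
  flipped <- g$s2
  tmp <- flipped$a1; flipped$a1 <- flipped$a2; flipped$a2 <- tmp
  flipped$z <- -flipped$z
  orig <- ldsc_rg(g$s1, g$s2, g$ld, n_blocks = 40)
  flip <- ldsc_rg(g$s1, flipped, g$ld, n_blocks = 40)
  expect_equal(flip$rg, orig$rg, tolerance = 1e-12)

  # strand-ambiguous markers are dropped from the intersection
  amb <- g$s2
  amb$a1[1:100] <- "A"; amb$a2[1:100] <- "T"
  fit <- ldsc_rg(g$s1, amb, g$ld, n_blocks = 40)
  expect_equal(fit$dropped_alleles, 100L)
  expect_equal(fit$m_snps, 3900)
})

test_that("block jackknife agrees with brute-force refitting per block", {
  g <- small_gwas(seed = 61, h2_1 = 0.4, h2_2 = 0.4, rg = 0, m = 1000)
  nb <- 10
  fit <- ldsc_h2(g$s1, g$ld, n_blocks = nb)
  # oracle: weighted lm on the data with each contiguous block removed
  ord <- order(g$ld$chr, g$ld$bp)
  x <- g$ld$l2[ord]; y <- g$s1$z[ord]^2; w <- 1 / pmax(x, 1)
  blocks <- as.integer(cut(seq_along(x), nb, labels = FALSE))
  theta <- vapply(seq_len(nb), function(j) {
    keep <- blocks != j
    co <- coef(lm(y ~ x, weights = w, subset = keep))
    unname(co[2]) * length(x) / mean(g$s1$n)
  }, numeric(1))
  se_oracle <- sqrt((nb - 1) / nb * sum((theta - mean(theta))^2))
  expect_equal(fit$h2_se, se_oracle, tolerance = 1e-8)
})

test_that("nonpositive heritability makes rg undefined with a clear error", {
  g <- small_gwas(seed = 71, h2_1 = 0, h2_2 = 0.3, rg = 0, m = 2000)
  # force a decisively negative slope for trait 1
  set.seed(81)
  g$s1$z <- sqrt(pmax(2 - g$ld$l2 / max(g$ld$l2), 0.1)) * rnorm(nrow(g$s1))
  expect_error(ldsc_rg(g$s1, g$s2, g$ld, n_blocks = 20),
               "nonpositive heritability")
})

test_that("rg tables are validated on load", {
  path <- withr::local_tempfile(fileext = ".tsv")
  pairs <- t(combn(default_disorders(), 2))
  df <- data.frame(disorder1 = pairs[, 1], disorder2 = pairs[, 2],
                   rg = runif(21, -0.2, 0.7), se = 0.1)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_rg_table(path)
  expect_equal(nrow(got), 21)
  expect_true(all(got$pair == pair_key(got$disorder1, got$disorder2)))

  dup <- rbind(df, data.frame(disorder1 = "SCZ", disorder2 = "ADHD",
                              rg = 0.1, se = 0.1))
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rg_table(path), "duplicate")

  bad <- df; bad$rg[1] <- 1.5
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rg_table(path), "1.25")

  # a 20-row table against a 21-pair imaging vector names the missing pair
  short <- df[-1, ]
  img <- setNames(runif(21), pair_key(df$disorder1, df$disorder2))
  err <- tryCatch(correlation_of_correlations(img, short),
                  error = conditionMessage)
  expect_match(err, pair_key(df$disorder1[1], df$disorder2[1]), fixed = TRUE)
})
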