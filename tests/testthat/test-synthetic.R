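test_that("generators are deterministic in the seed and vary across seeds", {
  sc1 <- default_panel_scenario(seed = 9)
  p1 <- gen_effect_panel(sc1)
  p2 <- gen_effect_panel(sc1)
  expect_identical(p1$profiles$SCZ$values$d, p2$profiles$SCZ$values$d)
  p3 <- gen_effect_panel(default_panel_scenario(seed = 10))
  expect_false(identical(p1$profiles$SCZ$values$d, p3$profiles$SCZ$values$d))

  g1 <- gen_gwas_pair(gwas_scenario(m_snps = 1000, seed = 4))
  g2 <- gen_gwas_pair(gwas_scenario(m_snps = 1000, seed = 4))
  expect_identical(g1$s1$z, g2$s1$z)
  g3 <- gen_gwas_pair(gwas_scenario(m_snps = 1000, seed = 5))
  expect_false(identical(g1$s1$z, g3$s1$z))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_effect_panel(default_panel_scenario(seed = 1)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("default scenario reproduces the published study shape", {
  panel <- gen_effect_panel(default_panel_scenario(seed = 2))
  expect_equal(panel_disorders(panel), default_disorders())
  n_ph <- vapply(panel$profiles, function(p) nrow(p$values), integer(1))
  expect_equal(unname(n_ph[c("SCZ", "OCD", "Epilepsy")]), c(75L, 74L, 41L))
  tab <- pairwise_table(panel, n_perm = 1, seed = 1)
  expect_setequal(unique(tab$df), c(73L, 72L, 39L))
  # means land near the published profile summaries (3 se band)
  s <- panel_summary(panel)
  scz <- s[s$disorder == "SCZ", ]
  expect_lt(abs(scz$mean_d - (-0.22)), 3 * scz$se_mean)
})

test_that("uncorrelated targets give near-null sample correlations", {
  sc <- panel_scenario(LETTERS[1:4], diag(4), seed = 17)
  tab <- pairwise_table(gen_effect_panel(sc), n_perm = 1, seed = 1)
  # null r at n = 75 has sd ~ 0.116; 0.45 is a ~4-sigma bound per pair
  expect_true(all(abs(tab$r) < 0.45))
})

test_that("strong targets are recovered within the Fisher-z sampling band", {
  target <- matrix(c(1, 0.81, 0.81, 1), 2)
  hits <- vapply(1:200, function(i) {
    sc <- panel_scenario(c("X", "Y"), target, seed = 3000 + i)
    panel <- gen_effect_panel(sc)
    xy <- intersect_phenotypes(panel$profiles$X, panel$profiles$Y)
    abs(correlate(xy$d_a, xy$d_b) - 0.81) <= 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("a degenerate unit-correlation target yields exactly collinear draws", {
  target <- matrix(1, 2, 2)
  sc <- panel_scenario(c("X", "Y"), target, scales = c(1, 2), seed = 6)
  panel <- gen_effect_panel(sc)
  xy <- intersect_phenotypes(panel$profiles$X, panel$profiles$Y)
  expect_equal(correlate(xy$d_a, xy$d_b), 1, tolerance = 1e-12)
})

test_that("non-PSD targets are rejected naming the smallest eigenvalue", {
  m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  err <- tryCatch(panel_scenario(LETTERS[1:3], m, seed = 1),
                  error = conditionMessage)
  expect_match(err, "not positive semidefinite")
  expect_match(err, "-0.8")   # smallest eigenvalue ~ -0.81 is reported
  # and the PSD repair produces a usable matrix with unit diagonal
  fixed <- nearest_psd_corr(m)
  expect_equal(diag(fixed), rep(1, 3))
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-10)
})

test_that("null GWAS draws calibrate to unit mean chi-square", {
  m <- 20000
  g <- gen_gwas_pair(gwas_scenario(m_snps = m, h2_1 = 0, h2_2 = 0, rg = 0,
                                   seed = 12))
  expect_lt(abs(mean(g$s1$z^2) - 1), 3 * sqrt(2 / m))
  expect_lt(abs(mean(g$s2$z^2) - 1), 3 * sqrt(2 / m))
})

test_that("the z1*z2 product is linear in the LD score with the stated slope", {
  sc <- gwas_scenario(m_snps = 20000, n1 = 50000, n2 = 50000,
                      h2_1 = 0.3, h2_2 = 0.3, rg = 0.68, seed = 13)
  g <- gen_gwas_pair(sc)
  fit <- lm(I(g$s1$z * g$s2$z) ~ g$ld$l2)
  slope_true <- sqrt(sc$n1 * sc$n2 * sc$h2_1 * sc$h2_2) * sc$rg / sc$m_snps
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - slope_true), 3 * est["Std. Error"])
})

test_that("spiked records fail exactly their designated filter", {
  g <- gen_gwas_pair(gwas_scenario(m_snps = 1000, seed = 14),
                     spike = c(info = 5L, mhc = 3L, missing_ref = 2L,
                               low_ref_maf = 2L))
  expect_equal(nrow(g$s1), 1012)
  out <- filter_sumstats(g$s1, g$ref_maf)
  log <- attr(out, "filter_log")
  expect_equal(unname(log[c("info", "mhc", "not_in_reference", "low_ref_maf")]),
               c(5L, 3L, 2L, 2L))
  expect_equal(nrow(out), 1000)
})

test_that("joint scenarios hit the requested coupling in the noise-free limit", {
  js <- gen_joint_scenario(coupling = 1, seed = 1)
  expect_equal(js$requested_coupling, 1)
  # PSD projection may distort ranks slightly; the reported achieved
  # coupling measures exactly that residual distortion
  expect_gt(js$achieved_coupling, 0.95)
  off <- js$scenario$target_corr[lower.tri(js$scenario$target_corr)]
  expect_true(all(abs(off) < 1))
  expect_error(gen_joint_scenario(coupling = 1.2), "not TRUE")

  # rg vectors must cover exactly the panel's pairs
  err <- tryCatch(gen_joint_scenario(rg_vector = default_rg_vector()[-1],
                                     coupling = 0.4),
                  error = conditionMessage)
  expect_match(err, "missing")
})

test_that("sample correlation matrices converge on the target as phenotypes grow", {
  # compare one pair's error at 75 phenotypes vs a registry 20x larger
  target <- matrix(c(1, 0.5, 0.5, 1), 2)
  sc75 <- panel_scenario(c("X", "Y"), target, seed = 8)
  p75 <- gen_effect_panel(sc75)
  xy <- intersect_phenotypes(p75$profiles$X, p75$profiles$Y)
  err75 <- abs(correlate(xy$d_a, xy$d_b) - 0.5)
  set.seed(8)
  big <- matrix(rnorm(2 * 10000), 10000, 2) %*% chol(target)
  err_big <- abs(cor(big[, 1], big[, 2]) - 0.5)
  expect_lt(err_big, 0.05)
  expect_lt(err_big, err75 + 0.05)
})
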