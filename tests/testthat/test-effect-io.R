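test_that("default registry has 41 regions and 75 phenotypes", {
  reg <- brain_registry()
  expect_equal(nrow(reg), 41)
  expect_equal(sum(reg$class == "cortical"), 34)
  expect_equal(sum(reg$class == "subcortical"), 7)
  ph <- phenotype_registry(reg)
  expect_equal(nrow(ph), 75)
  expect_equal(length(unique(ph$region)), 41)
  expect_false(anyDuplicated(ph$phenotype) > 0)
})

test_that("profiles reject invalid phenotypes and implausible values", {
  bad_measure <- data.frame(region = "insula", measure = "subcortical_volume",
                            d = 0.1)
  expect_error(effect_size_profile("X", bad_measure), "invalid phenotypes")
  bad_region <- data.frame(region = "unknown_gyrus", measure = "thickness",
                           d = 0.1)
  expect_error(effect_size_profile("X", bad_region), "unknown region")
  huge <- data.frame(region = c("insula", "cuneus"),
                     measure = "thickness", d = c(0.1, 6))
  expect_error(effect_size_profile("X", huge), "implausible")
  dup <- data.frame(region = "insula", measure = "thickness", d = c(0.1, 0.2))
  expect_error(effect_size_profile("X", dup), "duplicate")
  expect_error(
    effect_size_profile("X",
                        data.frame(region = "insula", measure = "thickness", d = 0.1),
                        n_cases = c(thickness = 1), n_controls = c(thickness = 10)),
    ">= 2")
})

test_that("region names are canonicalized on input", {
  p <- effect_size_profile("X", data.frame(
    region = c("Insula ", "SUPERIORFRONTAL"), measure = "thickness",
    d = c(0.1, 0.2)))
  expect_setequal(p$values$region, c("insula", "superiorfrontal"))
  expect_equal(canonical_region("Superior Frontal"), "superior_frontal")
})

test_that("effect tables round-trip bit-identically through TSV", {
  panel <- make_masked_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(panel, path)
  back <- read_effect_table(path)
  expect_equal(panel_disorders(back), panel_disorders(panel))
  for (ds in panel_disorders(panel)) {
    expect_identical(back$profiles[[ds]]$values$d, panel$profiles[[ds]]$values$d)
    expect_identical(back$profiles[[ds]]$values$phenotype,
                     panel$profiles[[ds]]$values$phenotype)
  }
})

test_that("counts survive the TSV round trip per measure type", {
  p <- make_profile("A", n_cases = c(thickness = 100, surface_area = 90,
                                     subcortical_volume = 80),
                    n_controls = c(thickness = 200, surface_area = 190,
                                   subcortical_volume = 180))
  panel <- disorder_panel(list(p, make_profile("B", 1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(panel, path)
  back <- read_effect_table(path)
  expect_equal(back$profiles$A$n_cases[["surface_area"]], 90)
  expect_equal(back$profiles$A$n_controls[["subcortical_volume"]], 180)
  expect_null(back$profiles$B$n_cases)
})

test_that("malformed effect tables are rejected with line context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disorder\tregion\tmeasure\td",
               "A\tinsula\tthickness\t0.1",
               "A\tcuneus\tthickness\tnot_a_number"), path)
  expect_error(read_effect_table(path), "line 3")
  writeLines("disorder\tregion\tmeasure\td", path)
  expect_error(read_effect_table(path), "empty")
  writeLines(c("disorder\tregion\tmeasure\td",
               "A\tinsula\tthickness\t0.1",
               "A\tinsula\tthickness\t0.2"), path)
  expect_error(read_effect_table(path), "duplicate")
})

test_that("phenotype intersection reproduces the published overlap pattern", {
  panel <- make_masked_panel()
  full <- intersect_phenotypes(panel$profiles$A, panel$profiles$B)
  expect_equal(attr(full, "n_overlap"), 75)           # df 73
  one <- intersect_phenotypes(panel$profiles$A, panel$profiles$C)
  expect_equal(attr(one, "n_overlap"), 74)            # df 72
  epi <- intersect_phenotypes(panel$profiles$A, panel$profiles$D)
  expect_equal(attr(epi, "n_overlap"), 41)            # df 39
  # the single missing phenotype is surface area, so the epilepsy-like
  # profile still overlaps it on all 41 thickness+subcortical phenotypes
  epi_ocd <- intersect_phenotypes(panel$profiles$C, panel$profiles$D)
  expect_equal(attr(epi_ocd, "n_overlap"), 41)
})

test_that("phenotype intersection is symmetric and fails on disjoint masks", {
  panel <- make_masked_panel()
  ab <- intersect_phenotypes(panel$profiles$A, panel$profiles$D)
  ba <- intersect_phenotypes(panel$profiles$D, panel$profiles$A)
  expect_equal(ab$phenotype, ba$phenotype)
  expect_equal(ab$d_a, ba$d_b)
  expect_equal(ab$d_b, ba$d_a)
  ph <- phenotype_registry()
  th <- ph$phenotype[ph$measure == "thickness"]
  p1 <- make_profile("P1", mask = th)                     # no thickness
  p2 <- make_profile("P2", mask = setdiff(ph$phenotype, th))  # only thickness
  expect_error(intersect_phenotypes(p1, p2), "share only 0")
})

test_that("panels require unique labels and at least two profiles", {
  expect_error(disorder_panel(list(make_profile("A"))), "at least 2")
  expect_error(disorder_panel(list(make_profile("A"), make_profile("A", 1))),
               "duplicate")
})
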