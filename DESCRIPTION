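Package: neuroconcord
Title: Cross-Disorder Concordance of Structural Brain Effect-Size Profiles
    and Genetic Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares case-control structural-MRI effect-size profiles
    (regional Cohen's d for cortical thickness, cortical surface area and
    subcortical volume) across neuropsychiatric disorders.  Provides
    pairwise profile correlations with analytic, Bonferroni-adjusted and
    permutation-based significance; per-phenotype sign-concordance and
    Cochran's Q heterogeneity tests; a lightweight cross-trait LD-score
    regression with block-jackknife standard errors for genetic
    correlations from GWAS summary statistics; the rank correlation
    between the imaging and genetic similarity structures with
    leave-one-out diagnostics; and simulators that generate effect-size
    panels and summary-statistic pairs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
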