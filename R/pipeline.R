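# end-to-end orchestration: panel -> pairwise correlations -> region
# statistics -> genetic correlations (LDSC or file) -> correlation of
# correlations -> report bundle

#' Build a validated run configuration
#'
#' Exactly one imaging source (an effect-table path, a ready
#' `disorder_panel`, or a `panel_scenario` to simulate from) and at most
#' one genetic source (an rg-table path/data frame, or a named list of
#' sumstats with LD scores) must be supplied.
#'
#' @param effect_table path to an effect TSV (see [read_effect_table()])
#' @param panel a ready [disorder_panel()]
#' @param scenario a [panel_scenario()] to simulate a panel from
#' @param rg_table path to, or data frame of, precomputed genetic
#'   correlations (see [read_rg_table()])
#' @param sumstats named list of `sumstats` tables (or file paths), one
#'   per disorder, for the LD-score regression route
#' @param ld LD-score table (or path) when `sumstats` is used
#' @param ref_maf reference MAF vector (or path) for filtering; optional
#' @param method pairwise correlation method (default `"pearson"`)
#' @param concordance_method method for the correlation of correlations
#'   (default `"spearman"`)
#' @param n_perm permutation count for pairwise tables
#' @param m_tests Bonferroni denominator; default = number of pairs
#' @param n_blocks jackknife blocks for LDSC
#' @param seed master seed; every stochastic stage derives its stream
#'   from it
#' @return object of class `run_config`
#' @export
run_config <- function(effect_table = NULL, panel = NULL, scenario = NULL,
                       rg_table = NULL, sumstats = NULL, ld = NULL,
                       ref_maf = NULL, method = "pearson",
                       concordance_method = "spearman",
                       n_perm = 10000L, m_tests = NULL, n_blocks = 200L,
                       seed = 1L) {
  n_img <- sum(!vapply(list(effect_table, panel, scenario), is.null, logical(1)))
  if (n_img != 1L) {
    stop_validation("supply exactly one of effect_table, panel, scenario")
  }
  if (!is.null(rg_table) && !is.null(sumstats)) {
    stop_validation("supply at most one of rg_table, sumstats")
  }
  if (!is.null(sumstats) && is.null(ld)) {
    stop_validation("sumstats mode needs an LD-score table")
  }
  stopifnot(n_perm >= 1L, length(seed) == 1L, is.finite(seed))
  structure(list(effect_table = effect_table, panel = panel,
                 scenario = scenario, rg_table = rg_table,
                 sumstats = sumstats, ld = ld, ref_maf = ref_maf,
                 method = method, concordance_method = concordance_method,
                 n_perm = as.integer(n_perm), m_tests = m_tests,
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full concordance pipeline
#'
#' Executes panel loading/simulation, the pairwise correlation table,
#' region-level sign and heterogeneity tables, the genetic-correlation
#' stage (LD-score regression over all pairs, or a precomputed table),
#' and - when genetic correlations are available - the correlation of
#' correlations with leave-one-out diagnostics.
#'
#' @param cfg a [run_config()]
#' @return list of class `concord_bundle` with elements `panel`,
#'   `pairwise`, `summary`, `sign_table`, `q_table`, `rg`, `concordance`,
#'   `config`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  panel <- stage("effect_size_io", {
    if (!is.null(cfg$panel)) cfg$panel
    else if (!is.null(cfg$effect_table)) read_effect_table(cfg$effect_table)
    else gen_effect_panel(cfg$scenario)
  })
  pairwise <- stage("concordance", {
    pairwise_table(panel, method = cfg$method, n_perm = cfg$n_perm,
                   seed = cfg$seed, m = cfg$m_tests)
  })
  signs <- stage("region_stats", region_sign_table(panel))
  qtab <- stage("region_stats", region_q_table(panel))
  rg <- stage("genetics", {
    if (!is.null(cfg$rg_table)) {
      if (is.character(cfg$rg_table)) read_rg_table(cfg$rg_table) else cfg$rg_table
    } else if (!is.null(cfg$sumstats)) {
      ss <- lapply(cfg$sumstats, function(s)
        if (is.character(s)) read_sumstats(s) else s)
      ld <- if (is.character(cfg$ld)) read_ldscores(cfg$ld) else cfg$ld
      ref <- if (is.character(cfg$ref_maf)) read_ref_maf(cfg$ref_maf) else cfg$ref_maf
      rg_table(ss, ld, ref_maf = ref, n_blocks = cfg$n_blocks)
    }
  })
  concord <- if (!is.null(rg)) {
    stage("correlation_of_correlations", {
      correlation_of_correlations(pairwise, rg,
                                  method = cfg$concordance_method,
                                  seed = derive_seed(cfg$seed, "concordance"))
    })
  }
  structure(list(panel = panel, pairwise = pairwise,
                 summary = panel_summary(panel), sign_table = signs,
                 q_table = qtab, rg = rg, concordance = concord,
                 config = cfg),
            class = "concord_bundle")
}

#' Write the report bundle to a directory
#'
#' Emits `pairwise.tsv`, `summary.tsv`, `regions_sign.tsv`,
#' `regions_q.tsv` (omitted, with a message, when no phenotype has usable
#' sample sizes), `rg.tsv` and `concordance.tsv` when computed, a
#' `manifest.json` recording package version, seed and configuration, and
#' (optionally) a correlation heatmap and a genetic-vs-imaging scatter as
#' PDF figures.  TSV outputs are deterministic: the same configuration
#' and seed reproduce identical bytes.
#'
#' @param bundle a `concord_bundle` from [run_pipeline()]
#' @param dir output directory (created if needed)
#' @param figures also write the PDF figures (default TRUE)
#' @return named character vector of written file paths, invisibly
#' @export
write_report <- function(bundle, dir, figures = TRUE) {
  stopifnot(inherits(bundle, "concord_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop_validation("output directory '%s' not writable", dir)
  files <- c(pairwise = file.path(dir, "pairwise.tsv"))
  write_pairwise_table(bundle$pairwise, files[["pairwise"]])

  files[["summary"]] <- file.path(dir, "summary.tsv")
  write_tsv_precise(bundle$summary, files[["summary"]])

  files[["regions_sign"]] <- file.path(dir, "regions_sign.tsv")
  write_tsv_precise(bundle$sign_table, files[["regions_sign"]])

  if (!is.null(bundle$q_table) && nrow(bundle$q_table)) {
    files[["regions_q"]] <- file.path(dir, "regions_q.tsv")
    write_tsv_precise(bundle$q_table, files[["regions_q"]])
  } else {
    message("regions_q.tsv omitted: no phenotype had usable sample sizes")
  }
  if (!is.null(bundle$rg)) {
    files[["rg"]] <- file.path(dir, "rg.tsv")
    write_tsv_precise(bundle$rg, files[["rg"]])
  }
  if (!is.null(bundle$concordance)) {
    cc <- bundle$concordance
    files[["concordance"]] <- file.path(dir, "concordance.tsv")
    loo <- cc$loo
    out <- data.frame(
      statistic = c("rho", "p", "n_pairs",
                    if (!is.null(loo)) paste0("loo_rho_excl_", names(loo))),
      value = sprintf("%.17g", c(cc$rho, cc$p, cc$n_pairs, unname(loo))),
      stringsAsFactors = FALSE)
    utils::write.table(out, files[["concordance"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files[["manifest"]] <- file.path(dir, "manifest.json")
  cfg <- bundle$config
  manifest <- list(
    package = "neuroconcord",
    version = as.character(utils::packageVersion("neuroconcord")),
    seed = cfg$seed, method = cfg$method,
    concordance_method = cfg$concordance_method,
    n_perm = cfg$n_perm, n_blocks = cfg$n_blocks,
    m_tests = cfg$m_tests %||% attr(bundle$pairwise, "m_tests"),
    disorders = panel_disorders(bundle$panel),
    files = basename(unname(files)))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (figures) {
    files[["heatmap"]] <- file.path(dir, "correlation_heatmap.pdf")
    save_quiet(plot_correlation_heatmap(bundle$pairwise), files[["heatmap"]])
    if (!is.null(bundle$concordance)) {
      files[["scatter"]] <- file.path(dir, "concordance_scatter.pdf")
      save_quiet(plot_concordance_scatter(bundle$pairwise, bundle$rg,
                                          bundle$concordance),
                 files[["scatter"]])
    }
  }
  invisible(files)
}

write_tsv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

save_quiet <- function(plot, path) {
  grDevices::pdf(path, width = 7, height = 6)
  on.exit(grDevices::dev.off())
  print(plot)
}

#' Heatmap of the pairwise correlation matrix
#'
#' @param tab a [pairwise_table()]
#' @return a ggplot object
#' @export
plot_correlation_heatmap <- function(tab) {
  labs <- sort(unique(c(tab$disorder1, tab$disorder2)))
  grid <- expand.grid(d1 = labs, d2 = labs, stringsAsFactors = FALSE)
  grid$key <- pair_key(grid$d1, grid$d2)
  rv <- stats::setNames(tab$r, tab$pair)
  grid$r <- ifelse(grid$d1 == grid$d2, 1, unname(rv[grid$key]))
  ggplot2::ggplot(grid, ggplot2::aes(x = d1, y = d2, fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Cross-disorder effect-size profile correlations") +
    ggplot2::theme_minimal()
}

#' Scatter of genetic vs imaging correlations
#'
#' @param tab a [pairwise_table()]
#' @param rg genetic correlation table
#' @param concordance optional `concordance_result` for the annotation
#' @return a ggplot object
#' @export
plot_concordance_scatter <- function(tab, rg, concordance = NULL) {
  al <- align_pairs(tab, rg)
  df <- data.frame(pair = names(al$imaging), imaging = unname(al$imaging),
                   genetic = unname(al$genetic), stringsAsFactors = FALSE)
  if (!is.null(rg$se)) {
    se <- stats::setNames(rg$se, rg$pair)
    df$se <- unname(se[df$pair])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = genetic, y = imaging)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = pair), size = 2) +
    ggplot2::labs(x = "genetic correlation (rg)",
                  y = "effect-size profile correlation",
                  color = "disorder pair") +
    ggplot2::theme_minimal()
  if (!is.null(df$se)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = genetic - se,
                   xmax = genetic + se),
      height = 0, color = "grey60")
  }
  if (!is.null(concordance)) {
    p <- p + ggplot2::annotate(
      "text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
      label = sprintf("rho = %.2f, p = %.3g", concordance$rho, concordance$p))
  }
  p
}
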