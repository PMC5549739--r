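#' Configure an end-to-end GRS + sign-test run
#'
#' @param catalog,vcf,panel Input file paths.
#' @param focal,reference Super-population codes compared (difference and
#'   sign test are focal minus/versus reference).
#' @param exclude_pops Population codes excluded in an additional
#'   continental-only sensitivity comparison (e.g. `c("ACB", "ASW")` for
#'   admixed African-ancestry samples); when empty only the main comparison
#'   runs.
#' @param hla [genomic_region()] excluded from the catalog; `NULL` disables.
#' @param p_threshold Genome-wide significance cutoff for the catalog.
#' @param r2_threshold LD pruning cutoff; used when `prune = TRUE`.
#' @param prune Whether to LD-prune (disable for catalogs that are already
#'   pruned, like published GRS SNP lists).
#' @param diff_threshold Large-frequency-difference cutoff for the subset
#'   sign test.
#' @param missing_policy Passed to [compute_grs()].
#' @param alternative Passed to [sign_test()].
#' @param prefer Dosage source preference, passed to [read_vcf()].
#' @return A `run_config` list.
#' @export
run_config <- function(catalog, vcf, panel,
                       focal = "AFR", reference = "EUR",
                       exclude_pops = character(),
                       hla = hla_region(), p_threshold = 5e-8,
                       r2_threshold = 0.2, prune = TRUE,
                       diff_threshold = 0.2,
                       missing_policy = "rescale",
                       alternative = "greater",
                       prefer = "DS") {
  stopifnot(focal != reference)
  structure(list(catalog = catalog, vcf = vcf, panel = panel,
                 focal = focal, reference = reference,
                 exclude_pops = exclude_pops, hla = hla,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 prune = prune, diff_threshold = diff_threshold,
                 missing_policy = missing_policy, alternative = alternative,
                 prefer = prefer),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(vals$hla)) vals$hla <- do.call(genomic_region, vals$hla)
  do.call(run_config, vals)
}

#' Run the full catalog -> prune -> score -> sign-test pipeline
#'
#' Executes the whole analysis: catalog loading, genome-wide significance
#' filtering, HLA exclusion, deduplication, VCF dosage extraction with allele
#' harmonization, optional greedy LD pruning, GRS computation, per-group
#' summaries, the focal-vs-reference Welch mean comparison (plus a
#' continental-only sensitivity comparison when `exclude_pops` is set),
#' per-group risk-allele frequencies, the binomial sign test and the
#' large-difference subset analysis. Fully deterministic: no randomness
#' outside the inputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage TSV artifacts and a
#'   JSON + text report are written there.
#' @return A `grs_report` list: `stages` (funnel counts), `summary_pop`,
#'   `summary_super`, `cdf`, `comparison`, `comparison_continental`,
#'   `freq_focal`, `freq_ref`, `sign_test`, `diff_summary`,
#'   `subset_sign_test`, `prune`, `scores`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name) function(e) stop("pipeline stage '", name, "' failed: ",
                                           conditionMessage(e), call. = FALSE)
  stages <- list()

  cat0 <- tryCatch(read_risk_catalog(config$catalog), error = stage("catalog"))
  stages$catalog_rows <- nrow(cat0)
  cat1 <- filter_genome_wide(cat0, config$p_threshold)
  stages$genome_wide <- nrow(cat1)
  cat2 <- if (is.null(config$hla)) cat1 else exclude_region(cat1, config$hla)
  stages$after_hla <- nrow(cat2)
  cat3 <- dedupe_catalog(cat2)
  stages$after_dedupe <- nrow(cat3)

  panel <- tryCatch(read_panel(config$panel), error = stage("panel"))
  dosage <- tryCatch(read_vcf(config$vcf, cat3, panel, prefer = config$prefer),
                     error = stage("vcf"))
  stages$matched_in_vcf <- ncol(dosage) - 1L

  prune <- NULL
  if (isTRUE(config$prune)) {
    prune <- greedy_prune(dosage, threshold = config$r2_threshold)
    dosage <- apply_prune(dosage, prune)
  }
  stages$after_prune <- ncol(dosage) - 1L

  scores <- compute_grs(dosage, panel, missing_policy = config$missing_policy)
  summary_pop <- summarize_grs(scores, "population")
  summary_super <- summarize_grs(scores, "super_population")
  cdf <- grs_cdf(scores, "super_population")
  comparison <- compare_grs_means(scores, config$focal, config$reference)
  comparison_cont <- if (length(config$exclude_pops) > 0L) {
    compare_grs_means(scores, config$focal, config$reference,
                      exclude = config$exclude_pops)
  } else NULL

  freq_focal <- allele_freq(dosage, panel, config$focal)
  freq_ref <- allele_freq(dosage, panel, config$reference)
  st <- sign_test(freq_focal, freq_ref, alternative = config$alternative)
  ds <- diff_summary(freq_focal, freq_ref, threshold = config$diff_threshold)
  sst <- subset_sign_test(freq_focal, freq_ref,
                          threshold = config$diff_threshold,
                          alternative = config$alternative)

  report <- structure(
    list(stages = tibble::tibble(stage = names(stages),
                                 n = unlist(stages, use.names = FALSE)),
         summary_pop = summary_pop, summary_super = summary_super,
         cdf = cdf, comparison = comparison,
         comparison_continental = comparison_cont,
         freq_focal = freq_focal, freq_ref = freq_ref,
         sign_test = st, diff_summary = ds, subset_sign_test = sst,
         prune = prune, scores = scores,
         match_report = match_report(dosage), config = config),
    class = "grs_report")

  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

write_report_artifacts <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(report$scores, file.path(out_dir, "scores.tsv"))
  readr::write_tsv(report$summary_pop, file.path(out_dir, "summary_population.tsv"))
  readr::write_tsv(report$summary_super, file.path(out_dir, "summary_super.tsv"))
  readr::write_tsv(report$cdf, file.path(out_dir, "cdf.tsv"))
  readr::write_tsv(report$freq_focal, file.path(out_dir, "freq_focal.tsv"))
  readr::write_tsv(report$freq_ref, file.path(out_dir, "freq_ref.tsv"))
  readr::write_tsv(report$stages, file.path(out_dir, "stages.tsv"))
  if (!is.null(report$match_report)) {
    readr::write_tsv(report$match_report, file.path(out_dir, "match_report.tsv"))
  }
  if (!is.null(report$prune)) {
    writeLines(report$prune$kept, file.path(out_dir, "pruned_kept.txt"))
    readr::write_tsv(report$prune$removed, file.path(out_dir, "pruned_removed.tsv"))
  }
  json <- list(stages = report$stages,
               summary_super = report$summary_super,
               comparison = tidy(report$comparison),
               sign_test = glance(report$sign_test),
               diff_summary = report$diff_summary,
               subset_sign_test = glance(report$subset_sign_test))
  if (!is.null(report$comparison_continental)) {
    json$comparison_continental <- tidy(report$comparison_continental)
  }
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(report_render(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render a pipeline report as text
#'
#' Produces the stage funnel, a summary table per population sorted by
#' median burden, the mean comparisons, and the sign-test paragraph. Fails
#' loudly on a report with empty sections rather than silently omitting
#' them.
#'
#' @param report A `grs_report`.
#' @return Character vector of report lines.
#' @export
report_render <- function(report) {
  stopifnot(inherits(report, "grs_report"))
  if (nrow(report$summary_pop) == 0L || nrow(report$summary_super) == 0L) {
    stop("report has empty group summaries; refusing to render", call. = FALSE)
  }
  fmt_summary <- function(s) {
    c(sprintf("%-8s %5s %8s %6s %6s %6s %6s %6s",
              "group", "n", "mean", "min", "q25", "median", "q75", "max"),
      sprintf("%-8s %5d %8.2f %6.1f %6.1f %6.1f %6.1f %6.1f",
              s$group, s$n, s$mean, s$min, s$q25, s$median, s$q75, s$max))
  }
  cmp_lines <- function(cmp, label) {
    c(sprintf("%s: mean(%s) - mean(%s) = %.2f risk alleles", label,
              cmp$group_a, cmp$group_b, cmp$diff),
      sprintf("  Welch t = %.2f, df = %.1f, two-sided p = %.3g",
              cmp$statistic, cmp$df, cmp$p_value))
  }
  st <- report$sign_test
  sst <- report$subset_sign_test
  ds <- report$diff_summary
  lines <- c(
    "== GRS burden and polygenic sign-test report ==",
    "",
    "-- stage funnel --",
    sprintf("  %-16s %d", report$stages$stage, report$stages$n),
    "",
    "-- GRS by population (sorted by median burden) --",
    fmt_summary(report$summary_pop),
    "",
    "-- GRS by super-population --",
    fmt_summary(report$summary_super),
    "",
    "-- mean comparisons --",
    cmp_lines(report$comparison, "main"),
    if (!is.null(report$comparison_continental)) {
      cmp_lines(report$comparison_continental,
                sprintf("continental-only (excluding %s)",
                        paste(report$comparison_continental$excluded,
                              collapse = ",")))
    },
    "",
    "-- sign test --",
    sprintf("  %d of %d informative variants at higher risk-allele frequency in %s (p0 = 1/2)",
            st$n_higher, st$n_informative, report$config$focal),
    sprintf("  exact binomial p (%s) = %.4g", st$alternative, st$p_value),
    sprintf("  |f diff| range: %.3f to %.3f; %d of %d variants > %.2f",
            ds$min_abs_diff, ds$max_abs_diff, ds$n_large, ds$n_total,
            ds$threshold),
    sprintf("  large-difference subset: %d of %d higher in %s, p = %.4g",
            sst$n_higher, sst$n_informative, report$config$focal, sst$p_value))
  lines
}

#' @export
print.grs_report <- function(x, ...) {
  cat(report_render(x), sep = "\n")
  invisible(x)
}
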