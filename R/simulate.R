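#' Configure a two-population drift/selection simulation
#'
#' The simulator draws, for each of `n_variants` unlinked biallelic SNPs, an
#' ancestral risk-allele frequency `p` and then one frequency per population
#' from the Balding-Nichols model, `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' `F = fst` -- mean `p`, variance `F p (1-p)`. Under the neutral regime
#' (`delta = 0`) the two populations' frequencies are exchangeable draws
#' around the shared ancestor. The selection regime shifts the *focal*
#' population's risk-allele frequency on the logit scale by `delta`
#' (see [shift_frequency()]), the simplest directional alternative in which
#' every risk allele tends to be more common in the focal group. Genotypes
#' are drawn per individual as Binomial(2, f) (Hardy-Weinberg). Optional LD
#' blocks of correlated variants exercise pruning.
#'
#' @param n_variants Number of SNPs `L` (default 147).
#' @param n_per_pop Diploid samples per population (default 300).
#' @param fst Divergence parameter in (0, 1); default 0.15, a typical
#'   continental-scale value.
#' @param ancestral Ancestral frequency distribution:
#'   `list(dist = "uniform", lo =, hi =)` or `list(dist = "beta", a =, b =)`.
#'   Default Uniform(0.05, 0.95) -- GWAS-ascertained risk variants are common,
#'   with no strong frequency skew.
#' @param delta Logit-scale selection shift applied to the focal population
#'   (0 = neutral).
#' @param ld_blocks Optional tibble/data frame with columns `size` and
#'   `fidelity`: each block turns `size` consecutive variants into an LD
#'   cluster by copying the block seed's genotypes and redrawing each entry
#'   independently with probability `1 - fidelity`; members share the seed's
#'   population frequencies (and chromosome) so the truth table remains
#'   exact.
#' @param clamp Two frequencies; population frequencies are clamped inside
#'   this interval (default `c(0.01, 0.99)`) so no simulated variant is
#'   monomorphic.
#' @param emit_ds If `TRUE`, [emit_dataset()] also writes a DS FORMAT field
#'   (hard call plus small truncated noise), exercising the dosage path.
#' @param seed Integer seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 147, n_per_pop = 300, fst = 0.15,
                       ancestral = list(dist = "uniform", lo = 0.05, hi = 0.95),
                       delta = 0, ld_blocks = NULL,
                       clamp = c(0.01, 0.99), emit_ds = FALSE, seed = 1) {
  stopifnot(n_variants >= 1, n_per_pop >= 1, fst > 0, fst < 1,
            length(clamp) == 2L, clamp[1] > 0, clamp[2] < 1, clamp[1] < clamp[2],
            ancestral$dist %in% c("uniform", "beta"))
  structure(list(n_variants = as.integer(n_variants),
                 n_per_pop = as.integer(n_per_pop), fst = fst,
                 ancestral = ancestral, delta = delta, ld_blocks = ld_blocks,
                 clamp = clamp, emit_ds = isTRUE(emit_ds),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Logit-scale frequency shift
#'
#' `f' = logistic(logit(f) + delta)`, clamped to `clamp`. Monotone in
#' `delta`; identity at `delta = 0`.
#'
#' @param f Frequencies in (0, 1).
#' @param delta Logit shift.
#' @param clamp Clamping interval.
#' @return Shifted frequencies.
#' @export
shift_frequency <- function(f, delta, clamp = c(0.01, 0.99)) {
  out <- stats::plogis(stats::qlogis(f) + delta)
  pmin(pmax(out, clamp[1]), clamp[2])
}

#' Draw per-variant true population frequencies
#'
#' Sets the seed from `config` and draws the truth table: ancestral
#' frequency, the two Balding-Nichols population frequencies (focal
#' frequency logit-shifted by `delta`), and simulated genomic coordinates
#' (variants spread over chromosomes 1-22, clear of the default HLA window).
#'
#' @param config A [sim_config()].
#' @return Truth tibble: `variant_id`, `chrom`, `pos`, `ancestral_p`,
#'   `f_focal`, `f_ref`, `shifted`.
#' @export
draw_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw_frequencies_impl(config)
}

draw_frequencies_impl <- function(config) {
  L <- config$n_variants
  p <- switch(config$ancestral$dist,
    uniform = stats::runif(L, config$ancestral$lo, config$ancestral$hi),
    beta    = stats::rbeta(L, config$ancestral$a, config$ancestral$b))
  F <- config$fst
  bn <- function(p) stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  cl <- function(f) pmin(pmax(f, config$clamp[1]), config$clamp[2])
  f_focal <- cl(bn(p))
  f_ref <- cl(bn(p))
  if (config$delta != 0) {
    f_focal <- shift_frequency(f_focal, config$delta, config$clamp)
  }
  chrom <- as.character(rep(1:22, each = ceiling(L / 22), length.out = L))
  # an LD block must sit on one chromosome or pruning could never see it, and
  # its members share the seed's frequencies so the truth table stays exact
  for (b in ld_block_index(config$ld_blocks, L)) {
    chrom[b$members] <- chrom[b$seed]
    p[b$members] <- p[b$seed]
    f_focal[b$members] <- f_focal[b$seed]
    f_ref[b$members] <- f_ref[b$seed]
  }
  tibble::tibble(
    variant_id = sprintf("rs%06d", seq_len(L)),
    chrom = chrom,
    pos = 40e6 + 1e6 * (seq_len(L) - 1),   # clear of the chr6 HLA window
    ancestral_p = p, f_focal = f_focal, f_ref = f_ref,
    shifted = config$delta != 0)
}

# Binomial(2, f) genotype matrix (samples x variants), with optional LD blocks
draw_genotypes <- function(freqs, config, prefix) {
  n <- config$n_per_pop
  L <- nrow(freqs)
  g <- matrix(stats::rbinom(n * L, 2L, rep(freqs$f, each = n)), nrow = n)
  blocks <- ld_block_index(config$ld_blocks, L)
  for (b in blocks) {
    seed_col <- g[, b$seed]
    for (j in b$members) {
      redraw <- stats::runif(n) < (1 - b$fidelity)
      col <- seed_col
      col[redraw] <- stats::rbinom(sum(redraw), 2L, freqs$f[j])
      g[, j] <- col
    }
  }
  rownames(g) <- sprintf("%s%04d", prefix, seq_len(n))
  colnames(g) <- freqs$variant_id
  g
}

# expand ld_blocks spec into per-block seed/member column indices
ld_block_index <- function(ld_blocks, L) {
  if (is.null(ld_blocks) || nrow(as.data.frame(ld_blocks)) == 0L) return(list())
  ld_blocks <- as.data.frame(ld_blocks)
  stopifnot(all(c("size", "fidelity") %in% names(ld_blocks)))
  out <- list()
  at <- 1L
  for (i in seq_len(nrow(ld_blocks))) {
    size <- as.integer(ld_blocks$size[i])
    if (at + size - 1L > L) break
    out[[i]] <- list(seed = at, members = seq(at + 1L, length.out = size - 1L),
                     fidelity = ld_blocks$fidelity[i])
    at <- at + size
  }
  out
}

#' Simulate a two-population dataset in memory
#'
#' Runs the full generative model (frequencies, then Hardy-Weinberg
#' genotypes, then optional LD blocks) and returns ready-to-analyse objects:
#' a dosage table whose risk allele is the simulated ALT allele, a panel with
#' focal super-population `"FOC"` and reference `"REF"`, a matching catalog
#' tibble and the truth table.
#'
#' @param config A [sim_config()].
#' @return List with elements `truth`, `dosage` (a `dosage_tbl`), `panel`,
#'   `catalog`, `config`.
#' @export
sim_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- draw_frequencies_impl(config)
  g_focal <- draw_genotypes(dplyr::rename(truth, f = "f_focal"), config, "FOC")
  g_ref <- draw_genotypes(dplyr::rename(truth, f = "f_ref"), config, "REF")
  g <- rbind(g_focal, g_ref)
  panel <- tibble::tibble(
    sample_id = rownames(g),
    population = rep(c("FOC1", "REF1"), each = config$n_per_pop),
    super_population = rep(c("FOC", "REF"), each = config$n_per_pop))
  catalog <- tibble::tibble(
    variant_id = truth$variant_id, chrom = truth$chrom, pos = truth$pos,
    risk_allele = "G", other_allele = "A", trait = "SimulatedTrait",
    assoc_p = 1e-9)
  vi <- dplyr::mutate(catalog, ref = "A", alt = "G",
                      orientation = "risk_is_alt", ambiguous_palindrome = FALSE,
                      source = "GT")
  list(truth = truth, dosage = new_dosage_tbl(g, vi), panel = panel,
       catalog = catalog, config = config)
}

#' Emit a simulated dataset as catalog TSV + VCF + panel files
#'
#' Writes the files the real-data pipeline consumes: a native-format risk
#' catalog (risk allele = simulated ALT `G`, other `A`), a VCF 4.2 with GT
#' (and DS when `emit_ds`), a two-group panel and the truth table. Output is
#' byte-identical across runs with the same config (fixed number formatting,
#' `\n` line endings).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List `truth`, `paths` (named: catalog, vcf, panel, truth),
#'   `config`.
#' @export
emit_dataset <- function(config, dir) {
  sim <- sim_dataset(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(catalog = file.path(dir, "catalog.tsv"),
                vcf = file.path(dir, "genotypes.vcf"),
                panel = file.path(dir, "panel.tsv"),
                truth = file.path(dir, "truth.tsv"))

  cat_lines <- c(
    paste(c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
            "trait", "assoc_p"), collapse = "\t"),
    sprintf("%s\t%s\t%d\t%s\t%s\t%s\t%s",
            sim$catalog$variant_id, sim$catalog$chrom,
            as.integer(sim$catalog$pos), sim$catalog$risk_allele,
            sim$catalog$other_allele, sim$catalog$trait,
            format(sim$catalog$assoc_p, scientific = TRUE)))
  writeLines(cat_lines, paths$catalog)

  writeLines(c("sample\tpop\tsuper_pop",
               sprintf("%s\t%s\t%s", sim$panel$sample_id, sim$panel$population,
                       sim$panel$super_population)),
             paths$panel)

  tr <- sim$truth
  writeLines(c(paste(names(tr), collapse = "\t"),
               sprintf("%s\t%s\t%d\t%.10f\t%.10f\t%.10f\t%s",
                       tr$variant_id, tr$chrom, as.integer(tr$pos),
                       tr$ancestral_p, tr$f_focal, tr$f_ref,
                       ifelse(tr$shifted, "TRUE", "FALSE"))),
             paths$truth)

  g <- t(as_dosage_matrix(sim$dosage))  # variants x samples, values 0/1/2
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  if (config$emit_ds) {
    noise <- matrix(stats::runif(length(g), -0.05, 0.05), nrow = nrow(g))
    ds <- pmin(2, pmax(0, g + noise))
    body <- matrix(sprintf("%s:%.3f", gt_str, ds), nrow = nrow(g))
    fmt <- "GT:DS"
  } else {
    body <- gt_str
    fmt <- "GT"
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=signburden-simulator",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (config$emit_ds)
                '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sim$panel$sample_id), collapse = "\t"))
  records <- sprintf("%s\t%d\t%s\tA\tG\t.\tPASS\t.\t%s\t%s",
                     tr$chrom, as.integer(tr$pos), tr$variant_id, fmt,
                     apply(body, 1L, paste, collapse = "\t"))
  writeLines(c(header, records), paths$vcf)

  list(truth = sim$truth, paths = paths, config = config)
}
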