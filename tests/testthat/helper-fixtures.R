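# Shared fixtures and independent oracles, built in code at test time.

# --- catalog fixtures -------------------------------------------------------

make_catalog <- function(variant_id, chrom = "1", pos = seq_along(variant_id) * 1e6,
                         risk_allele = "G", other_allele = "A",
                         trait = "Trait", assoc_p = 1e-9) {
  tibble::tibble(variant_id = variant_id, chrom = chrom, pos = pos,
                 risk_allele = risk_allele, other_allele = other_allele,
                 trait = trait, assoc_p = assoc_p)
}

write_native_catalog <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

write_gwascat_export <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("SNPS", "CHR_ID", "CHR_POS", "STRONGEST SNP-RISK ALLELE",
                    "DISEASE/TRAIT", "P-VALUE"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

# --- panel / VCF fixtures ---------------------------------------------------

toy_panel <- function() {
  tibble::tibble(sample_id = paste0("S", 1:6),
                 population = rep(c("YRI", "CEU"), each = 3),
                 super_population = rep(c("AFR", "EUR"), each = 3))
}

write_panel_file <- function(panel, path = tempfile(fileext = ".panel")) {
  writeLines(c("sample\tpop\tsuper_pop",
               sprintf("%s\t%s\t%s", panel$sample_id, panel$population,
                       panel$super_population)), path)
  path
}

# Minimal VCF writer for hand-built records
write_toy_vcf <- function(records, samples, format = "GT",
                          path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", format,
            r$calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# --- independent oracles ----------------------------------------------------

# Pearson r^2 straight from the sums-of-products covariance formula
r2_formula_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}

# One-sided binomial upper tail by direct pmf summation
binom_tail_oracle <- function(k, n) {
  if (k > n) return(0)
  sum(choose(n, k:n)) / 2^n
}

# Welch statistic from the textbook formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# dosage_tbl straight from a numeric matrix (samples x variants)
dosage_from_matrix <- function(m, chrom = "1", pos = seq_len(ncol(m)) * 1e6,
                               assoc_p = 1e-9) {
  vi <- tibble::tibble(variant_id = colnames(m), chrom = chrom, pos = pos,
                       risk_allele = "G", other_allele = "A",
                       trait = "Trait", assoc_p = assoc_p,
                       ref = "A", alt = "G", orientation = "risk_is_alt",
                       ambiguous_palindrome = FALSE, source = "GT")
  signburden:::new_dosage_tbl(m, vi)
}

# sign-test p straight from simulated genotypes, used by power/type-I checks
sim_sign_p <- function(seed, delta = 0, fst = 0.15, L = 147, n = 300) {
  cfg <- sim_config(n_variants = L, n_per_pop = n, fst = fst, delta = delta,
                    seed = seed)
  sim <- sim_dataset(cfg)
  ff <- allele_freq(sim$dosage, sim$panel, "FOC")
  fr <- allele_freq(sim$dosage, sim$panel, "REF")
  sign_test(ff, fr)$p_value
}

# Post-hoc oracle for greedy_prune output
prune_invariants_hold <- function(dosage, pr) {
  m <- as_dosage_matrix(dosage)
  vi <- variant_info(dosage)
  chrom <- setNames(vi$chrom, vi$variant_id)
  # every kept same-chromosome pair is below threshold
  for (chr in unique(chrom[pr$kept])) {
    ids <- pr$kept[chrom[pr$kept] == chr]
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
      r2 <- pairwise_r2(m[, ids[i]], m[, ids[j]])
      if (!is.na(r2) && r2 >= pr$threshold) return(FALSE)
    }
  }
  # every removed variant has a kept culprit at or above threshold
  if (nrow(pr$removed) > 0) {
    for (k in seq_len(nrow(pr$removed))) {
      if (!pr$removed$culprit_id[k] %in% pr$kept) return(FALSE)
      r2 <- pairwise_r2(m[, pr$removed$variant_id[k]],
                        m[, pr$removed$culprit_id[k]])
      if (is.na(r2) || r2 < pr$threshold) return(FALSE)
    }
  }
  # partition
  setequal(c(pr$kept, pr$removed$variant_id), vi$variant_id) &&
    length(intersect(pr$kept, pr$removed$variant_id)) == 0
}
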