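#' Per-variant risk-allele frequency in a population group
#'
#' For each variant the frequency is the risk-allele dosage total over the
#' group's non-missing samples divided by the number of chromosomes observed
#' (`2 x` the non-missing sample count); dosage input makes the allele total
#' possibly fractional. Variants missing in every sample of the group are
#' dropped with a message -- downstream tests cannot use them.
#'
#' @param dosage A `dosage_tbl`.
#' @param panel Panel tibble.
#' @param group Group code at `level`.
#' @param level `"super_population"` (default) or `"population"`.
#' @param exclude Population codes to drop from the group.
#' @return Tibble `variant_id`, `group`, `f`, `n_chrom`.
#' @export
allele_freq <- function(dosage, panel,
                        group, level = c("super_population", "population"),
                        exclude = character()) {
  level <- match.arg(level)
  ids <- panel$sample_id[panel[[level]] == group & !panel$population %in% exclude]
  m <- as_dosage_matrix(dosage)
  m <- m[rownames(m) %in% ids, , drop = FALSE]
  if (nrow(m) == 0L) stop("group '", group, "' has no samples in the dosage table",
                          call. = FALSE)
  n_obs <- colSums(!is.na(m))
  f <- colSums(m, na.rm = TRUE) / (2 * n_obs)
  out <- tibble::tibble(variant_id = colnames(m), group = group,
                        f = unname(f), n_chrom = unname(2L * n_obs))
  if (any(out$n_chrom == 0L)) {
    message(sum(out$n_chrom == 0L),
            " variant(s) missing in all '", group, "' samples were dropped")
    out <- out[out$n_chrom > 0L, , drop = FALSE]
  }
  out
}

#' Read / write frequency tables
#'
#' Frequency tables are the exchange format for the sign test, so published
#' per-population frequencies can be fed straight in without genotypes.
#'
#' @param path TSV with columns `variant_id`, `group`, `f` and optionally
#'   `n_chrom`.
#' @return Frequency tibble.
#' @export
read_freq_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("variant_id", "group", "f")
  if (!all(need %in% names(out))) {
    stop("frequency table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"n_chrom" %in% names(out)) out$n_chrom <- NA_integer_
  if (any(out$f < 0 | out$f > 1, na.rm = TRUE)) {
    stop("frequencies outside [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(out[, c("variant_id", "group", "f", "n_chrom")])
}

#' @rdname read_freq_table
#' @param freq Frequency tibble.
#' @export
write_freq_table <- function(freq, path) {
  readr::write_tsv(freq, path)
  invisible(path)
}

#' Binomial (QTL) sign test for systematic frequency differences
#'
#' Under neutral drift, each risk allele is equally likely to be at higher
#' frequency in either population, so the count of variants at higher
#' frequency in the focal group is Binomial(n, 1/2). The test counts
#' `n_higher = #\{f_focal > f_ref\}` over the informative (non-tied) variants
#' and computes the exact binomial tail. The default alternative is
#' `"greater"` -- the directional hypothesis that risk alleles are
#' systematically more frequent in the focal group; `"two.sided"` doubles the
#' smaller tail (capped at 1). Exact ties are excluded, following classical
#' sign-test practice.
#'
#' @param freq_focal,freq_ref Frequency tibbles for the focal and reference
#'   groups covering the same variants (extra variants in either are dropped
#'   by the inner join).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `sign_test_result`: `n_total`, `n_ties`, `n_informative`,
#'   `n_higher`, `p0 = 0.5`, `p_value`, `alternative`.
#' @export
sign_test <- function(freq_focal, freq_ref,
                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  merged <- dplyr::inner_join(
    dplyr::select(freq_focal, "variant_id", f_focal = "f"),
    dplyr::select(freq_ref, "variant_id", f_ref = "f"),
    by = "variant_id")
  merged <- merged[!is.na(merged$f_focal) & !is.na(merged$f_ref), , drop = FALSE]
  n_total <- nrow(merged)
  ties <- merged$f_focal == merged$f_ref
  n_ties <- sum(ties)
  n_inf <- n_total - n_ties
  n_higher <- sum(merged$f_focal > merged$f_ref)
  if (n_inf == 0L) {
    warning("no informative (non-tied) variants; p = 1", call. = FALSE)
    p <- 1
  } else {
    p <- binom_tail_p(n_higher, n_inf, alternative)
  }
  structure(list(n_total = n_total, n_ties = n_ties, n_informative = n_inf,
                 n_higher = n_higher, p0 = 0.5, p_value = p,
                 alternative = alternative,
                 variants = merged$variant_id,
                 higher = merged$variant_id[merged$f_focal > merged$f_ref]),
            class = "sign_test_result")
}

# exact binomial tail at p0 = 1/2
binom_tail_p <- function(k, n, alternative) {
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  if (alternative == "greater") return(upper)
  lower <- stats::pbinom(k, n, 0.5)                          # P(X <= k)
  min(1, 2 * min(upper, lower))
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat("Binomial sign test for risk-allele frequency differences\n")
  cat(sprintf("  %d of %d informative variants at higher frequency in the focal group\n",
              x$n_higher, x$n_informative))
  if (x$n_ties > 0) cat("  (", x$n_ties, " exact ties excluded)\n", sep = "")
  cat(sprintf("  exact binomial p (%s, p0 = 1/2) = %.4g\n",
              x$alternative, x$p_value))
  invisible(x)
}

#' @rdname sign_test
#' @param x A `sign_test_result`.
#' @param ... Unused.
#' @method tidy sign_test_result
#' @export
tidy.sign_test_result <- function(x, ...) {
  tibble::tibble(estimate = if (x$n_informative > 0)
                   x$n_higher / x$n_informative else NA_real_,
                 statistic = x$n_higher, parameter = x$n_informative,
                 p.value = x$p_value, alternative = x$alternative)
}

#' @rdname sign_test
#' @method glance sign_test_result
#' @export
glance.sign_test_result <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_ties = x$n_ties,
                 n_informative = x$n_informative, n_higher = x$n_higher,
                 p0 = x$p0, p.value = x$p_value)
}

#' Summary of absolute frequency differences
#'
#' Reports the extremes of `|f_focal - f_ref|` and how many variants exceed
#' the large-difference cutoff (strict `>`, configurable).
#'
#' @inheritParams sign_test
#' @param threshold Large-difference cutoff; default 0.2.
#' @return One-row tibble: `n_total`, `min_abs_diff`, `max_abs_diff`,
#'   `threshold`, `n_large`, `prop_large`.
#' @export
diff_summary <- function(freq_focal, freq_ref, threshold = 0.2) {
  d <- abs_freq_diffs(freq_focal, freq_ref)
  tibble::tibble(n_total = length(d),
                 min_abs_diff = if (length(d)) min(d) else NA_real_,
                 max_abs_diff = if (length(d)) max(d) else NA_real_,
                 threshold = threshold,
                 n_large = sum(d > threshold),
                 prop_large = if (length(d)) sum(d > threshold) / length(d)
                              else NA_real_)
}

abs_freq_diffs <- function(freq_focal, freq_ref) {
  merged <- dplyr::inner_join(
    dplyr::select(freq_focal, "variant_id", f_focal = "f"),
    dplyr::select(freq_ref, "variant_id", f_ref = "f"),
    by = "variant_id")
  stats::setNames(abs(merged$f_focal - merged$f_ref), merged$variant_id)
}

#' Sign test on the largest frequency differences
#'
#' Restricts the sign test to variants whose absolute frequency difference
#' exceeds `threshold` -- the subset where drift alone is least likely to
#' explain a directional excess.
#'
#' @inheritParams diff_summary
#' @param alternative Passed to [sign_test()].
#' @return A `sign_test_result` with the subset's variant ids in
#'   `$variants`.
#' @export
subset_sign_test <- function(freq_focal, freq_ref, threshold = 0.2,
                             alternative = c("greater", "two.sided")) {
  d <- abs_freq_diffs(freq_focal, freq_ref)
  keep <- names(d)[d > threshold]
  if (length(keep) == 0L) {
    warning("no variants exceed the frequency-difference threshold; p = 1",
            call. = FALSE)
    res <- structure(list(n_total = 0L, n_ties = 0L, n_informative = 0L,
                          n_higher = 0L, p0 = 0.5, p_value = 1,
                          alternative = match.arg(alternative),
                          variants = character(), higher = character()),
                     class = "sign_test_result")
    return(res)
  }
  sign_test(freq_focal[freq_focal$variant_id %in% keep, , drop = FALSE],
            freq_ref[freq_ref$variant_id %in% keep, , drop = FALSE],
            alternative = alternative)
}
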