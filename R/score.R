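#' Compute the unweighted genetic risk score
#'
#' The GRS of a sample is the sum of its risk-allele dosages over the variant
#' panel -- the number of risk-increasing alleles carried, with no effect-size
#' weighting. With hard genotype calls and no missingness the score is an
#' integer in `[0, 2M]` for `M` variants.
#'
#' Missing calls are never counted as zero (that would bias scores downward).
#' Under the default `"rescale"` policy a sample's sum over its `m_used`
#' non-missing variants is multiplied by `M / m_used`, keeping samples with
#' different marker availability on the full-panel scale; `"raw"` reports the
#' plain sum. Samples with no non-missing variant are dropped with a warning.
#'
#' @param dosage A `dosage_tbl`.
#' @param panel Optional panel tibble; when given, population labels are
#'   joined onto the result.
#' @param missing_policy `"rescale"` (default) or `"raw"`.
#' @return Tibble with columns `sample_id`, `m_used`, `grs` (plus
#'   `population` / `super_population` when a panel is supplied).
#' @export
compute_grs <- function(dosage, panel = NULL,
                        missing_policy = c("rescale", "raw")) {
  missing_policy <- match.arg(missing_policy)
  m <- as_dosage_matrix(dosage)
  if (ncol(m) == 0L) stop("dosage table has no variants", call. = FALSE)
  m_total <- ncol(m)
  m_used <- unname(rowSums(!is.na(m)))
  grs <- unname(rowSums(m, na.rm = TRUE))
  if (missing_policy == "rescale") {
    grs <- grs * m_total / m_used  # NaN when m_used == 0; dropped below
  }
  out <- tibble::tibble(sample_id = rownames(m), m_used = as.integer(m_used),
                        grs = grs)
  if (any(out$m_used == 0L)) {
    warning(sum(out$m_used == 0L),
            " sample(s) with no non-missing variants were excluded",
            call. = FALSE)
    out <- out[out$m_used > 0L, , drop = FALSE]
  }
  if (!is.null(panel)) {
    out <- dplyr::left_join(out, panel, by = "sample_id")
  }
  out
}

#' Summarize GRS by population group
#'
#' One row per group with the sample count, mean, minimum, 25th percentile,
#' median, 75th percentile and maximum of the score, sorted by median burden
#' (ascending). Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7) so reports are bit-reproducible.
#'
#' @param scores Score tibble from [compute_grs()] (with panel labels).
#' @param level Grouping column: `"population"` or `"super_population"`.
#' @return A `grs_summary` tibble: `group`, `n`, `mean`, `min`, `q25`,
#'   `median`, `q75`, `max`.
#' @export
summarize_grs <- function(scores, level = c("super_population", "population")) {
  level <- match.arg(level)
  if (!level %in% names(scores)) {
    stop("scores lack a '", level, "' column; pass a panel to compute_grs()",
         call. = FALSE)
  }
  if (any(is.na(scores[[level]]))) {
    stop("some scored samples have no '", level, "' label", call. = FALSE)
  }
  out <- scores |>
    dplyr::group_by(group = .data[[level]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$grs),
      min = min(.data$grs),
      q25 = stats::quantile(.data$grs, 0.25, type = 7, names = FALSE),
      median = stats::median(.data$grs),
      q75 = stats::quantile(.data$grs, 0.75, type = 7, names = FALSE),
      max = max(.data$grs),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$median, .data$group)
  class(out) <- c("grs_summary", class(out))
  out
}

#' Cumulative-distribution coordinates of the GRS per group
#'
#' Empirical CDF coordinates suitable for plotting score distributions of
#' several groups on one axis.
#'
#' @inheritParams summarize_grs
#' @return Tibble `group`, `grs`, `cdf` with `cdf` the empirical
#'   P(GRS <= grs) within the group.
#' @export
grs_cdf <- function(scores, level = c("super_population", "population")) {
  level <- match.arg(level)
  scores |>
    dplyr::group_by(group = .data[[level]]) |>
    dplyr::arrange(.data$grs, .by_group = TRUE) |>
    dplyr::mutate(cdf = seq_len(dplyr::n()) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("group", "grs", "cdf")
}

#' Compare mean GRS between two groups (Welch t-test)
#'
#' Two-sided Welch unequal-variance t-test of the group score means. The
#' degenerate case of two constant, identical groups returns `t = 0, p = 1`
#' rather than an error.
#'
#' @param scores Score tibble with group labels.
#' @param group_a,group_b Group codes (levels of `level`); the difference is
#'   `mean(a) - mean(b)`.
#' @param level Grouping column name.
#' @param exclude Population codes to drop (requires a `population` column);
#'   supports continental-only sensitivity comparisons.
#' @return A `grs_mean_comparison` object; see [tidy()] / [glance()].
#' @export
compare_grs_means <- function(scores, group_a, group_b,
                              level = c("super_population", "population"),
                              exclude = character()) {
  level <- match.arg(level)
  if (length(exclude) > 0L) {
    scores <- dplyr::filter(scores, !.data$population %in% exclude)
  }
  xa <- scores$grs[scores[[level]] == group_a]
  xb <- scores$grs[scores[[level]] == group_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("both groups need at least two samples", call. = FALSE)
  }
  ht <- tryCatch(
    stats::t.test(xa, xb, var.equal = FALSE),
    error = function(e) NULL  # "data are essentially constant"
  )
  if (is.null(ht)) {
    diff <- mean(xa) - mean(xb)
    if (diff != 0) stop("constant groups with different means", call. = FALSE)
    res <- list(statistic = 0, parameter = NA_real_, p.value = 1,
                conf.int = c(0, 0))
  } else {
    res <- ht
  }
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(xa), n_b = length(xb),
                 mean_a = mean(xa), mean_b = mean(xb),
                 diff = mean(xa) - mean(xb),
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 conf_low = res$conf.int[1], conf_high = res$conf.int[2],
                 excluded = exclude),
            class = "grs_mean_comparison")
}

#' @export
print.grs_mean_comparison <- function(x, ...) {
  cat("Welch two-sample comparison of mean GRS\n")
  cat(sprintf("  %s (n=%d, mean=%.2f)  vs  %s (n=%d, mean=%.2f)\n",
              x$group_a, x$n_a, x$mean_a, x$group_b, x$n_b, x$mean_b))
  if (length(x$excluded)) {
    cat("  excluding populations:", paste(x$excluded, collapse = ", "), "\n")
  }
  cat(sprintf("  difference in means = %.2f risk alleles\n", x$diff))
  cat(sprintf("  t = %.3f, df = %.1f, two-sided p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname compare_grs_means
#' @param x A `grs_mean_comparison`.
#' @param ... Unused.
#' @method tidy grs_mean_comparison
#' @export
tidy.grs_mean_comparison <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b,
                 estimate = x$diff, statistic = x$statistic,
                 parameter = x$df, p.value = x$p_value,
                 conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @rdname compare_grs_means
#' @method glance grs_mean_comparison
#' @export
glance.grs_mean_comparison <- function(x, ...) {
  tibble::tibble(n_a = x$n_a, n_b = x$n_b, mean_a = x$mean_a,
                 mean_b = x$mean_b, estimate = x$diff,
                 statistic = x$statistic, parameter = x$df,
                 p.value = x$p_value)
}
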