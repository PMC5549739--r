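#' Plot GRS distribution by group
#'
#' Median burden per group with bars spanning the 25th-75th percentiles,
#' groups ordered by median -- the standard way to eyeball a systematic
#' burden shift between populations.
#'
#' @param object A `grs_summary` from [summarize_grs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grs_summary
#' @export
autoplot.grs_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      group = factor(.data$group,
                                     levels = object$group[order(object$median)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                            linewidth = 1.2, colour = "grey40") +
    ggplot2::geom_point(size = 2.5, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "GRS (risk alleles)",
                  title = "Risk-allele burden by group",
                  subtitle = "point = median, bar = 25th-75th percentile") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.grs_summary
#' @param summary A `grs_summary`.
#' @export
plot_grs_summary <- function(summary) autoplot.grs_summary(summary)

#' Plot cumulative GRS distributions per group
#'
#' @param scores Score tibble from [compute_grs()] with group labels.
#' @param level Grouping column.
#' @return A ggplot of empirical CDFs.
#' @export
plot_grs_cdf <- function(scores, level = c("super_population", "population")) {
  level <- match.arg(level)
  df <- grs_cdf(scores, level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grs, y = .data$cdf,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "GRS (risk alleles)", y = "cumulative proportion",
                  colour = NULL,
                  title = "Cumulative distribution of risk-allele burden") +
    ggplot2::theme_minimal()
}

#' Plot focal-vs-reference risk-allele frequencies
#'
#' Scatter of per-variant risk-allele frequencies with the diagonal of
#' equality; under neutrality points straddle the diagonal symmetrically.
#'
#' @param freq_focal,freq_ref Frequency tibbles ([allele_freq()]).
#' @return A ggplot.
#' @export
plot_freq_comparison <- function(freq_focal, freq_ref) {
  df <- dplyr::inner_join(
    dplyr::select(freq_focal, "variant_id", f_focal = "f"),
    dplyr::select(freq_ref, "variant_id", f_ref = "f"),
    by = "variant_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_ref, y = .data$f_focal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "risk-allele frequency (reference)",
                  y = "risk-allele frequency (focal)",
                  title = "Per-variant risk-allele frequencies") +
    ggplot2::theme_minimal()
}
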