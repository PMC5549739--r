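#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation between two dosage vectors over
#' pairwise-complete samples (composite/genotypic LD: phase-free, defined on
#' unphased dosages). Returns `NA` when either vector is monomorphic over the
#' complete pairs or fewer than two complete pairs exist; callers treat such
#' pairs as unlinked.
#'
#' @param g1,g2 Numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (stats::var(g1) == 0 || stats::var(g2) == 0) return(NA_real_)
  stats::cor(g1, g2)^2
}

#' Greedy LD pruning of a variant panel
#'
#' Visits variants in a fixed order and keeps a variant only if its genotype
#' r-squared with every already-kept variant *on the same chromosome* is
#' below `threshold`; cross-chromosome pairs are never pruned. The default
#' order is genomic (chromosome, position, variant id); `order = "pvalue"`
#' visits by ascending association p-value so the most significant variant of
#' a correlated cluster is retained. Deterministic for a fixed order.
#'
#' @param dosage A `dosage_tbl` holding the reference genotypes used to
#'   estimate LD.
#' @param threshold r-squared cutoff in `(0, 1]`; default 0.2.
#' @param order `"position"` (default) or `"pvalue"`.
#' @return A `prune_result`: list with `kept` (variant ids, visit order),
#'   `removed` (tibble `variant_id`, `culprit_id`, `r2`), and `threshold`.
#' @export
greedy_prune <- function(dosage, threshold = 0.2, order = c("position", "pvalue")) {
  order <- match.arg(order)
  stopifnot(threshold > 0, threshold <= 1)
  vi <- variant_info(dosage)
  if (is.null(vi)) stop("dosage table lacks variant metadata", call. = FALSE)
  m <- as_dosage_matrix(dosage)

  ord <- if (order == "pvalue") {
    order(vi$assoc_p, vi$variant_id)
  } else {
    order(chrom_rank(vi$chrom), vi$pos, vi$variant_id)
  }
  ids <- vi$variant_id[ord]
  chroms <- vi$chrom[ord]

  kept <- character(0)
  kept_chrom <- character(0)
  removed <- list()
  for (j in seq_along(ids)) {
    id <- ids[j]
    same <- kept[kept_chrom == chroms[j]]
    culprit <- NA_character_; r2hit <- NA_real_
    for (k in same) {
      r2 <- pairwise_r2(m[, id], m[, k])
      if (!is.na(r2) && r2 >= threshold) {
        culprit <- k; r2hit <- r2
        break
      }
    }
    if (is.na(culprit)) {
      kept <- c(kept, id)
      kept_chrom <- c(kept_chrom, chroms[j])
    } else {
      removed[[length(removed) + 1L]] <-
        tibble::tibble(variant_id = id, culprit_id = culprit, r2 = r2hit)
    }
  }
  structure(list(kept = kept,
                 removed = if (length(removed)) dplyr::bind_rows(removed) else
                   tibble::tibble(variant_id = character(),
                                  culprit_id = character(), r2 = numeric()),
                 threshold = threshold),
            class = "prune_result")
}

# numeric ordering for 1..22 then X, Y, others
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[is.na(r)] <- 25
  r
}

#' @export
print.prune_result <- function(x, ...) {
  cat("LD pruning at r² <", x$threshold, "\n")
  cat("  kept:   ", length(x$kept), "variants\n")
  cat("  removed:", nrow(x$removed), "variants\n")
  invisible(x)
}

#' Keep only the LD-pruned variants of a dosage table
#'
#' @param dosage A `dosage_tbl`.
#' @param prune A `prune_result` from [greedy_prune()].
#' @return `dosage_tbl` restricted (and ordered) to the kept variants.
#' @export
apply_prune <- function(dosage, prune) {
  vi <- variant_info(dosage)
  keep <- vi$variant_id %in% prune$kept
  out <- dosage[, c("sample_id", vi$variant_id[keep]), drop = FALSE]
  class(out) <- c("dosage_tbl", class(tibble::tibble()))
  attr(out, "variant_info") <- vi[keep, , drop = FALSE]
  attr(out, "match_report") <- attr(dosage, "match_report")
  out
}
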