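#' Read a risk-variant catalog
#'
#' Parses the tab-delimited catalog of GWAS risk variants that defines a
#' genetic risk score. Two dialects are recognised: the NHGRI-EBI GWAS Catalog
#' export (columns `SNPS`, `CHR_ID`, `CHR_POS`, `STRONGEST SNP-RISK ALLELE`,
#' `DISEASE/TRAIT`, `P-VALUE`, where the risk allele is embedded as
#' `"rsID-X"`) and a simpler native layout with explicit columns
#' `variant_id`, `chrom`, `pos`, `risk_allele`, `other_allele`, `trait`,
#' `assoc_p`.
#'
#' Rows whose risk allele cannot be parsed to a single A/C/G/T base (for
#' example the GWAS Catalog's `"rsID-?"` sentinel) are not dropped silently:
#' they are returned in the `"rejected"` attribute with a reason, retrievable
#' with [rejected_variants()].
#'
#' @param path Path to a tab-delimited catalog file.
#' @param format `"auto"` (default, sniffed from the header), `"gwascatalog"`
#'   or `"native"`.
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `risk_allele`,
#'   `other_allele` (`NA` when the source does not report it), `trait`,
#'   `assoc_p`, carrying a `"rejected"` attribute (tibble of unparseable rows
#'   with a `reason` column).
#' @seealso [filter_genome_wide()], [exclude_region()], [dedupe_catalog()]
#' @export
read_risk_catalog <- function(path, format = c("auto", "gwascatalog", "native")) {
  format <- match.arg(format)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    stop("catalog file '", path, "' contains a header but no rows", call. = FALSE)
  }
  if (format == "auto") {
    format <- if ("SNPS" %in% names(raw)) "gwascatalog" else "native"
  }

  if (format == "gwascatalog") {
    required <- c("SNPS", "CHR_ID", "CHR_POS", "STRONGEST SNP-RISK ALLELE",
                  "DISEASE/TRAIT", "P-VALUE")
    check_columns(raw, required, path)
    allele <- parse_strongest_allele(raw[["STRONGEST SNP-RISK ALLELE"]])
    out <- tibble::tibble(
      variant_id   = raw[["SNPS"]],
      chrom        = raw[["CHR_ID"]],
      pos          = suppressWarnings(as.numeric(raw[["CHR_POS"]])),
      risk_allele  = allele,
      other_allele = NA_character_,
      trait        = raw[["DISEASE/TRAIT"]],
      assoc_p      = suppressWarnings(as.numeric(raw[["P-VALUE"]]))
    )
  } else {
    required <- c("variant_id", "chrom", "pos", "risk_allele", "trait", "assoc_p")
    check_columns(raw, required, path)
    out <- tibble::tibble(
      variant_id   = raw[["variant_id"]],
      chrom        = raw[["chrom"]],
      pos          = suppressWarnings(as.numeric(raw[["pos"]])),
      risk_allele  = toupper(raw[["risk_allele"]]),
      other_allele = if ("other_allele" %in% names(raw)) toupper(raw[["other_allele"]]) else NA_character_,
      trait        = raw[["trait"]],
      assoc_p      = suppressWarnings(as.numeric(raw[["assoc_p"]]))
    )
  }
  out$other_allele[!is.na(out$other_allele) & !out$other_allele %in% BASES] <- NA_character_

  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$risk_allele) | !out$risk_allele %in% BASES] <- "unknown risk allele"
  reason[is.na(reason) & (is.na(out$variant_id) | out$variant_id == "")] <- "missing variant id"
  reason[is.na(reason) & (is.na(out$pos) | out$pos < 1)] <- "invalid position"
  reason[is.na(reason) & !is.na(out$other_allele) &
           out$other_allele == out$risk_allele] <- "risk and other allele identical"

  rejected <- dplyr::mutate(out[!is.na(reason), , drop = FALSE], reason = reason[!is.na(reason)])
  kept <- out[is.na(reason), , drop = FALSE]
  kept$chrom <- sub("^chr", "", kept$chrom)
  attr(kept, "rejected") <- rejected
  kept
}

#' Rows rejected while reading a catalog
#'
#' @param catalog A catalog tibble from [read_risk_catalog()].
#' @return Tibble of rejected rows with a `reason` column (empty if none).
#' @export
rejected_variants <- function(catalog) {
  rej <- attr(catalog, "rejected")
  if (is.null(rej)) {
    rej <- tibble::tibble(variant_id = character(), chrom = character(),
                          pos = numeric(), risk_allele = character(),
                          other_allele = character(), trait = character(),
                          assoc_p = numeric(), reason = character())
  }
  rej
}

# "rs1800470-C" -> "C"; "rs999-?" -> NA
parse_strongest_allele <- function(x) {
  allele <- toupper(sub("^.*-", "", trimws(x)))
  allele[!allele %in% BASES] <- NA_character_
  allele
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("catalog file '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Keep genome-wide-significant variants
#'
#' @param catalog Catalog tibble.
#' @param threshold P-value cutoff; variants with `assoc_p <= threshold` are
#'   kept. Default `5e-8`, the conventional genome-wide significance level.
#' @return Filtered catalog tibble.
#' @export
filter_genome_wide <- function(catalog, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  dplyr::filter(catalog, !is.na(.data$assoc_p), .data$assoc_p <= threshold)
}

#' Define a genomic region
#'
#' Coordinates are 1-based; the interval is half-open `[start, end)` so that
#' adjacent regions never overlap.
#'
#' @param chrom Chromosome label (without a `chr` prefix).
#' @param start,end 1-based start (inclusive) and end (exclusive).
#' @return A `genomic_region` list.
#' @export
genomic_region <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, start >= 1, start < end)
  structure(list(chrom = sub("^chr", "", as.character(chrom)),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "genomic_region")
}

#' The extended HLA/MHC exclusion window
#'
#' Default window chr6:25,000,000-35,000,000 (GRCh37, half-open), a widely
#' used extended-MHC interval. The HLA region's long-range LD makes variants
#' there unsuitable for an independent-SNP score, so it is excluded by
#' default in [run_pipeline()].
#'
#' @param start,end Override the window bounds.
#' @return A `genomic_region`.
#' @export
hla_region <- function(start = 25e6, end = 35e6) genomic_region("6", start, end)

#' Exclude variants falling in a genomic region
#'
#' A variant is removed when its chromosome matches and
#' `start <= pos < end`. The removed rows are kept in the `"removed"`
#' attribute of the result.
#'
#' @param catalog Catalog tibble.
#' @param region A [genomic_region()]; defaults to [hla_region()].
#' @return Catalog tibble of kept variants; `attr(, "removed")` holds the
#'   excluded rows.
#' @export
exclude_region <- function(catalog, region = hla_region()) {
  stopifnot(inherits(region, "genomic_region"))
  inside <- catalog$chrom == region$chrom &
    !is.na(catalog$pos) & catalog$pos >= region$start & catalog$pos < region$end
  kept <- catalog[!inside, , drop = FALSE]
  attr(kept, "rejected") <- attr(catalog, "rejected")
  attr(kept, "removed") <- catalog[inside, , drop = FALSE]
  kept
}

#' Deduplicate a catalog by variant id
#'
#' A SNP reported for several traits appears once per trait in GWAS Catalog
#' exports; scoring must count it once. The first occurrence (input order)
#' wins. If the same rsID is listed with *different* risk alleles the
#' conflict is reported via a warning and the `"conflicts"` attribute rather
#' than silently merged; the first-seen allele is retained.
#'
#' @param catalog Catalog tibble.
#' @return Deduplicated catalog tibble; `attr(, "conflicts")` lists rsIDs
#'   carrying discordant risk alleles.
#' @export
dedupe_catalog <- function(catalog) {
  conflicts <- catalog |>
    dplyr::distinct(.data$variant_id, .data$risk_allele) |>
    dplyr::count(.data$variant_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts) > 0L) {
    warning("conflicting risk alleles for variant(s): ",
            paste(conflicts$variant_id, collapse = ", "),
            "; first occurrence retained", call. = FALSE)
  }
  out <- dplyr::distinct(catalog, .data$variant_id, .keep_all = TRUE)
  attr(out, "rejected") <- attr(catalog, "rejected")
  attr(out, "conflicts") <- catalog |>
    dplyr::filter(.data$variant_id %in% conflicts$variant_id)
  out
}

#' Write a normalized catalog TSV
#'
#' @param catalog Catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(catalog[, c("variant_id", "chrom", "pos", "risk_allele",
                               "other_allele", "trait", "assoc_p")], path)
  invisible(path)
}
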