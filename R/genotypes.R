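#' Read a sample-to-population panel file
#'
#' Parses a 1000 Genomes phase-3 style panel file: whitespace-delimited with
#' a header naming at least `sample`, `pop` and `super_pop` columns
#' (additional columns such as `gender` are ignored). Each population code
#' must map to exactly one super-population.
#'
#' @param path Panel file path.
#' @return Tibble with columns `sample_id`, `population`, `super_population`.
#' @export
read_panel <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  nm <- tolower(names(raw))
  col <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit) == 0L) {
      stop("panel file '", path, "' lacks a column named one of: ",
           paste(cands, collapse = ", "), call. = FALSE)
    }
    raw[[hit[1L]]]
  }
  panel <- tibble::tibble(
    sample_id        = as.character(col(c("sample", "sample_id"))),
    population       = as.character(col(c("pop", "population"))),
    super_population = as.character(col(c("super_pop", "super_population")))
  )
  dup <- panel$sample_id[duplicated(panel$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicated sample id(s) in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$population == "" | panel$super_population == "")) {
    stop("panel has samples with empty population labels", call. = FALSE)
  }
  multi <- panel |>
    dplyr::distinct(.data$population, .data$super_population) |>
    dplyr::count(.data$population) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    stop("population(s) mapped to more than one super-population: ",
         paste(multi$population, collapse = ", "), call. = FALSE)
  }
  panel
}

#' Resolve risk-allele orientation against VCF REF/ALT
#'
#' Determines how a GWAS-reported risk/other allele pair lines up with a VCF
#' record's REF/ALT pair. An exact match of the allele sets wins; otherwise a
#' reverse-complement (strand-flip) match wins; palindromic pairs (A/T, C/G)
#' that match without flipping are accepted as plus-strand -- 1000 Genomes
#' style data are plus-strand by construction -- but flagged
#' `ambiguous_palindrome` because strand cannot be proven from alleles alone.
#' When the other allele is unknown (`NA`) the risk allele alone is matched,
#' exact before flipped. Anything else is `unresolved`; such variants are
#' excluded from scoring and logged, never scored with a guess.
#'
#' @param risk,other Risk and other alleles (single bases; `other` may be
#'   `NA`). Vectorised.
#' @param ref,alt VCF REF and ALT alleles.
#' @return Tibble with columns `mode` (one of `risk_is_alt`, `risk_is_ref`,
#'   `flip_risk_is_alt`, `flip_risk_is_ref`, `unresolved`) and
#'   `ambiguous_palindrome` (logical).
#' @export
resolve_orientation <- function(risk, other, ref, alt) {
  n <- length(risk)
  stopifnot(length(other) == n, length(ref) == n, length(alt) == n)
  risk <- toupper(risk); other <- toupper(other)
  ref <- toupper(ref); alt <- toupper(alt)

  mode <- rep("unresolved", n)
  crisk <- complement_base(risk)
  cother <- complement_base(other)
  palindromic <- !is.na(ref) & !is.na(alt) & ref == complement_base(alt)

  valid <- risk %in% BASES & ref %in% BASES & alt %in% BASES & ref != alt
  other_known <- !is.na(other) & other %in% BASES
  known <- valid & other_known & other != risk

  exact <- known & ((risk == alt & other == ref) | (risk == ref & other == alt))
  flip  <- known & !exact &
    ((crisk == alt & cother == ref) | (crisk == ref & cother == alt))

  # a known other allele equal to risk is invalid, never fall back to
  # single-allele matching for it
  unknown <- valid & !other_known
  uex <- unknown & (risk == alt | risk == ref)
  ufl <- unknown & !uex & (crisk == alt | crisk == ref)

  mode[exact & risk == alt] <- "risk_is_alt"
  mode[exact & risk == ref] <- "risk_is_ref"
  mode[flip & crisk == alt] <- "flip_risk_is_alt"
  mode[flip & crisk == ref] <- "flip_risk_is_ref"
  mode[uex & risk == alt] <- "risk_is_alt"
  mode[uex & risk == ref] <- "risk_is_ref"
  mode[ufl & crisk == alt] <- "flip_risk_is_alt"
  mode[ufl & crisk == ref] <- "flip_risk_is_ref"

  tibble::tibble(mode = mode,
                 ambiguous_palindrome = palindromic & mode != "unresolved")
}

new_dosage_tbl <- function(dosage, variant_info, match_report = NULL) {
  out <- tibble::as_tibble(as.data.frame(dosage, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(dosage)), out)
  class(out) <- c("dosage_tbl", class(tibble::tibble()))
  attr(out, "variant_info") <- variant_info
  attr(out, "match_report") <- match_report
  out
}

#' Variant metadata attached to a dosage table
#'
#' @param x A `dosage_tbl`.
#' @return Tibble of per-variant metadata (chrom, pos, alleles, orientation,
#'   dosage source).
#' @export
variant_info <- function(x) attr(x, "variant_info")

#' Per-variant match report from VCF extraction
#'
#' @param x A `dosage_tbl` from [read_vcf()].
#' @return Tibble with one row per catalog variant: `status` (`matched`,
#'   `missing`, `skipped`) and `reason`.
#' @export
match_report <- function(x) attr(x, "match_report")

#' Extract the numeric dosage matrix
#'
#' @param x A `dosage_tbl`.
#' @return Numeric samples x variants matrix of risk-allele dosages in
#'   `[0, 2]`, with `NA` for missing calls; rownames are sample ids.
#' @export
as_dosage_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' @export
print.dosage_tbl <- function(x, ...) {
  cat("<dosage_tbl> ", nrow(x), " samples x ", ncol(x) - 1L,
      " variants (risk-allele dosages)\n", sep = "")
  NextMethod()
}

#' Read risk-allele dosages for catalog variants from a VCF
#'
#' Matches VCF records to the catalog (by rsID first, then by chrom:pos),
#' resolves risk-allele orientation with [resolve_orientation()], and returns
#' the per-sample risk-allele dosage for every matched variant. The ALT
#' dosage comes from the `DS` FORMAT field when present (imputed data),
#' otherwise from the `GT` allele count; it is then transformed by the
#' orientation (`risk_is_ref` modes take `2 - d`). Multi-allelic records and
#' variants with unresolvable orientation are skipped and recorded in the
#' match report, as are catalog variants absent from the VCF.
#'
#' @param path VCF path (plain or bgzipped, v4.x).
#' @param catalog Catalog tibble ([read_risk_catalog()]).
#' @param panel Panel tibble ([read_panel()]); the VCF sample set must
#'   overlap it.
#' @param prefer `"DS"` (default) to use dosages when available, `"GT"` to
#'   force hard calls.
#' @return A `dosage_tbl` (samples x variants tibble) with variant metadata
#'   in [variant_info()] and the per-variant funnel in [match_report()].
#' @export
read_vcf <- function(path, catalog, panel, prefer = c("DS", "GT")) {
  prefer <- match.arg(prefer)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) {  # single-record VCFs drop to a named vector
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- tibble::as_tibble(as.data.frame(fix_mat, stringsAsFactors = FALSE))
  fix$POS <- as.numeric(fix$POS)
  fix$CHROM <- sub("^chr", "", fix$CHROM)
  fix$row <- seq_len(nrow(fix))

  as_record_matrix <- function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
    else m
  }
  gt_raw <- as_record_matrix(vcfR::extract.gt(vcf, element = "GT"))
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  ds_raw <- if (has_ds) {
    as_record_matrix(suppressWarnings(
      vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)))
  } else NULL

  vcf_samples <- colnames(gt_raw)
  common <- intersect(vcf_samples, panel$sample_id)
  if (length(common) == 0L) {
    stop("no VCF sample ids found in the panel", call. = FALSE)
  }
  if (length(common) < length(vcf_samples)) {
    warning(length(vcf_samples) - length(common),
            " VCF sample(s) absent from the panel were dropped", call. = FALSE)
  }

  report <- tibble::tibble(variant_id = catalog$variant_id,
                           status = "missing", reason = "not in VCF",
                           matched_by = NA_character_, source = NA_character_)
  dosage <- matrix(NA_real_, nrow = length(common), ncol = nrow(catalog),
                   dimnames = list(common, catalog$variant_id))
  vi <- dplyr::mutate(catalog, ref = NA_character_, alt = NA_character_,
                      orientation = NA_character_, ambiguous_palindrome = NA,
                      source = NA_character_)

  for (i in seq_len(nrow(catalog))) {
    hit <- fix$row[!is.na(fix$ID) & fix$ID == catalog$variant_id[i]]
    matched_by <- "rsid"
    if (length(hit) == 0L) {
      hit <- fix$row[fix$CHROM == catalog$chrom[i] & fix$POS == catalog$pos[i]]
      matched_by <- "position"
    }
    if (length(hit) == 0L) next
    hit <- hit[1L]
    ref <- fix$REF[hit]; alt <- fix$ALT[hit]
    if (is.na(alt) || grepl(",", alt)) {
      report[i, c("status", "reason", "matched_by")] <-
        list("skipped", "multiallelic record", matched_by)
      next
    }
    if (nchar(ref) != 1L || nchar(alt) != 1L) {
      report[i, c("status", "reason", "matched_by")] <-
        list("skipped", "non-SNP record", matched_by)
      next
    }
    ori <- resolve_orientation(catalog$risk_allele[i], catalog$other_allele[i],
                               ref, alt)
    if (ori$mode == "unresolved") {
      report[i, c("status", "reason", "matched_by")] <-
        list("skipped", "unresolved allele orientation", matched_by)
      next
    }
    use_ds <- prefer == "DS" && !is.null(ds_raw) && any(!is.na(ds_raw[hit, common]))
    d <- if (use_ds) {
      ds_raw[hit, common]
    } else {
      gt_to_alt_count(gt_raw[hit, common])
    }
    if (ori$mode %in% c("risk_is_ref", "flip_risk_is_ref")) d <- 2 - d
    dosage[, i] <- d
    src <- if (use_ds) "DS" else "GT"
    report[i, c("status", "reason", "matched_by", "source")] <-
      list("matched", NA_character_, matched_by, src)
    vi[i, c("ref", "alt", "orientation", "source")] <-
      list(ref, alt, ori$mode, src)
    vi$ambiguous_palindrome[i] <- ori$ambiguous_palindrome
  }

  keep <- report$status == "matched"
  out <- new_dosage_tbl(dosage[, keep, drop = FALSE],
                        vi[keep, , drop = FALSE], report)
  out
}

# "0/1", "1|1", "./." etc -> ALT allele count (NA for missing)
gt_to_alt_count <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == "." | a == "")) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
}

#' Restrict a dosage table to population groups
#'
#' Keeps samples whose super-population is in `groups`, optionally excluding
#' named populations -- e.g. restricting AFR to continental-African
#' populations by excluding the admixed ACB and ASW samples.
#'
#' @param dosage A `dosage_tbl`.
#' @param panel Panel tibble.
#' @param groups Super-population codes to keep.
#' @param exclude Population codes to drop within those groups.
#' @return Filtered `dosage_tbl`.
#' @export
subset_samples <- function(dosage, panel, groups, exclude = character()) {
  missing_groups <- setdiff(groups, panel$super_population)
  if (length(missing_groups) > 0L) {
    stop("group code(s) not in panel: ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  keep_ids <- panel$sample_id[panel$super_population %in% groups &
                                !panel$population %in% exclude]
  out <- dosage[dosage$sample_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no samples left after subsetting to groups ",
         paste(groups, collapse = ","), call. = FALSE)
  }
  class(out) <- c("dosage_tbl", class(tibble::tibble()))
  attr(out, "variant_info") <- attr(dosage, "variant_info")
  attr(out, "match_report") <- attr(dosage, "match_report")
  out
}
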