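test_that("panel files parse, with duplicates rejected by name", {
  panel <- read_panel(write_panel_file(tibble::tibble(
    sample_id = c("A1", "A2", "B1", "B2"),
    population = c("YRI", "YRI", "CEU", "CEU"),
    super_population = c("AFR", "AFR", "EUR", "EUR"))))
  expect_equal(nrow(panel), 4L)
  expect_equal(sort(unique(panel$super_population)), c("AFR", "EUR"))

  dup <- tibble::tibble(sample_id = c("A1", "A1"), population = "YRI",
                        super_population = "AFR")
  path <- tempfile()
  writeLines(c("sample\tpop\tsuper_pop",
               sprintf("%s\t%s\t%s", dup$sample_id, dup$population,
                       dup$super_population)), path)
  expect_error(read_panel(path), "A1")
})

test_that("simulated panels round-trip with the configured group sizes", {
  cfg <- sim_config(n_variants = 5, n_per_pop = 100, seed = 3)
  out <- emit_dataset(cfg, tempfile("panelrt"))
  panel <- read_panel(out$paths$panel)
  expect_equal(nrow(panel), 200L)
  expect_equal(as.vector(table(panel$super_population)[c("FOC", "REF")]),
               c(100L, 100L))
})

test_that("orientation resolution matches its stated cases", {
  expect_equal(resolve_orientation("G", "A", "A", "G")$mode, "risk_is_alt")
  expect_equal(resolve_orientation("T", "C", "A", "G")$mode, "flip_risk_is_ref")
  pal <- resolve_orientation("A", "T", "A", "T")
  expect_equal(pal$mode, "risk_is_ref")
  expect_true(pal$ambiguous_palindrome)
  expect_equal(resolve_orientation("C", "G", "A", "G")$mode, "unresolved")
})

test_that("orientation agrees with a set-based oracle over all 16 allele pairings", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- function(risk, other, ref, alt) {
    if (setequal(c(risk, other), c(ref, alt)) && risk != other) {
      if (risk == alt) "risk_is_alt" else "risk_is_ref"
    } else if (setequal(comp[c(risk, other)], c(ref, alt)) && risk != other) {
      if (comp[[risk]] == alt) "flip_risk_is_alt" else "flip_risk_is_ref"
    } else "unresolved"
  }
  grid <- expand.grid(risk = c("A", "C", "G", "T"), other = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  got <- resolve_orientation(grid$risk, grid$other, rep("A", 16), rep("G", 16))
  want <- mapply(oracle, grid$risk, grid$other, "A", "G")
  expect_equal(got$mode, unname(want))
})

test_that("orientation round-trip against itself never comes back unresolved", {
  pairs <- subset(expand.grid(risk = c("A", "C", "G", "T"),
                              other = c("A", "C", "G", "T"),
                              stringsAsFactors = FALSE), risk != other)
  res <- resolve_orientation(pairs$risk, pairs$other, pairs$risk, pairs$other)
  expect_true(all(res$mode == "risk_is_ref"))
})

toy_records <- function() list(
  list(chrom = "1", pos = 100, id = "rs1", ref = "A", alt = "G",
       calls = c("0/0", "0/1", "1/1", "0/1", "./.", "1|1")),
  list(chrom = "1", pos = 200, id = "rs2", ref = "A", alt = "G",
       calls = c("0/1", "0/0", "1/1", "1/1", "0/1", "0/0")),
  list(chrom = "1", pos = 300, id = "rs3", ref = "A", alt = "G",
       calls = c("0/0", "0/1", "0/1", "1/1", "0/0", "0/1")),
  list(chrom = "1", pos = 400, id = "rs4", ref = "A", alt = "G,T",
       calls = c("0/0", "0/1", "0/2", "1/1", "0/0", "0/1")),
  list(chrom = "1", pos = 500, id = "rs5", ref = "A", alt = "G",
       calls = c("0/0", "0/1", "1/1", "0/1", "0/0", "0/1")))

toy_catalog <- function() make_catalog(
  c("rs1", "rs2", "rs3", "rs5", "rs6"),
  pos = c(100, 200, 300, 500, 600),
  risk_allele = c("G", "A", "T", "C", "G"),
  other_allele = c("A", "G", "C", "G", "A"))

test_that("read_vcf reproduces a hand-coded dosage matrix with full funnel accounting", {
  path <- write_toy_vcf(toy_records(), paste0("S", 1:6))
  d <- read_vcf(path, toy_catalog(), toy_panel())
  m <- as_dosage_matrix(d)
  # rs1 risk=ALT: plain alt counts; rs2 risk=REF: 2-d; rs3 strand-flip to REF: 2-d
  expected <- cbind(rs1 = c(0, 1, 2, 1, NA, 2),
                    rs2 = c(1, 2, 0, 0, 1, 2),
                    rs3 = c(2, 1, 1, 0, 2, 1))
  rownames(expected) <- paste0("S", 1:6)
  expect_equal(m, expected)

  rep <- match_report(d)
  expect_equal(rep$status[rep$variant_id == "rs5"], "skipped")
  expect_match(rep$reason[rep$variant_id == "rs5"], "unresolved")
  expect_equal(rep$status[rep$variant_id == "rs6"], "missing")
  expect_false("rs4" %in% colnames(m))  # multiallelic never entered the catalog match
})

test_that("GT dosages of risk and other allele always sum to 2", {
  path <- write_toy_vcf(toy_records(), paste0("S", 1:6))
  cat_risk <- toy_catalog()[1:3, ]
  cat_other <- cat_risk
  names(cat_other)[names(cat_other) == "risk_allele"] <- "tmp"
  names(cat_other)[names(cat_other) == "other_allele"] <- "risk_allele"
  names(cat_other)[names(cat_other) == "tmp"] <- "other_allele"
  m1 <- as_dosage_matrix(read_vcf(path, cat_risk, toy_panel()))
  m2 <- as_dosage_matrix(read_vcf(path, cat_other, toy_panel()))
  ok <- !is.na(m1)
  expect_true(all((m1 + m2)[ok] == 2))
})

test_that("read_vcf is permutation-safe over record order", {
  recs <- toy_records()
  p1 <- write_toy_vcf(recs, paste0("S", 1:6))
  p2 <- write_toy_vcf(rev(recs), paste0("S", 1:6))
  m1 <- as_dosage_matrix(read_vcf(p1, toy_catalog(), toy_panel()))
  m2 <- as_dosage_matrix(read_vcf(p2, toy_catalog(), toy_panel()))
  expect_equal(m1, m2)
})

test_that("DS dosages are preferred and orientation arithmetic applies to them", {
  rec <- list(list(chrom = "1", pos = 100, id = "rs2", ref = "A", alt = "G",
                   calls = c("0/1:1.7", "0/0:0.1", "1/1:1.9",
                             "1/1:2.0", "0/1:0.9", "0/0:0.0")))
  cat <- make_catalog("rs2", pos = 100, risk_allele = "A", other_allele = "G")
  path <- write_toy_vcf(rec, paste0("S", 1:6), format = "GT:DS")
  m_ds <- as_dosage_matrix(read_vcf(path, cat, toy_panel(), prefer = "DS"))
  expect_equal(unname(m_ds[, "rs2"]), 2 - c(1.7, 0.1, 1.9, 2.0, 0.9, 0.0))
  m_gt <- as_dosage_matrix(read_vcf(path, cat, toy_panel(), prefer = "GT"))
  expect_equal(unname(m_gt[, "rs2"]), 2 - c(1, 0, 2, 2, 1, 0))
})

test_that("sample subsetting honours groups and exclusions", {
  path <- write_toy_vcf(toy_records(), paste0("S", 1:6))
  d <- read_vcf(path, toy_catalog(), toy_panel())
  afr <- subset_samples(d, toy_panel(), "AFR")
  expect_equal(afr$sample_id, c("S1", "S2", "S3"))
  expect_identical(subset_samples(d, toy_panel(), "AFR", exclude = character())$sample_id,
                   afr$sample_id)
  expect_error(subset_samples(d, toy_panel(), "EAS"), "EAS")

  # seven-population panel: excluding the two admixed codes keeps five
  panel7 <- tibble::tibble(
    sample_id = sprintf("P%02d", 1:14),
    population = rep(c("ACB", "ASW", "ESN", "GWD", "LWK", "MSL", "YRI"), each = 2),
    super_population = "AFR")
  sim_m <- matrix(1, nrow = 14, ncol = 1,
                  dimnames = list(panel7$sample_id, "rs1"))
  dd <- dosage_from_matrix(sim_m)
  kept <- subset_samples(dd, panel7, "AFR", exclude = c("ACB", "ASW"))
  kept_pops <- panel7$population[panel7$sample_id %in% kept$sample_id]
  expect_setequal(unique(kept_pops), c("ESN", "GWD", "LWK", "MSL", "YRI"))
  # matches a direct filter of the panel
  expect_equal(nrow(kept),
               sum(panel7$super_population == "AFR" &
                     !panel7$population %in% c("ACB", "ASW")))
})
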