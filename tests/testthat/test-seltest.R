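freq_tbl <- function(ids, f, group = "X") {
  tibble::tibble(variant_id = ids, group = group, f = f,
                 n_chrom = rep(100L, length(ids)))
}

test_that("allele frequencies follow the dosage arithmetic", {
  panel <- toy_panel()
  m <- rbind(S1 = c(1, 2, 2), S2 = c(1, 2, 2), S3 = c(1, 0, 2),
             S4 = c(1, 0, 1), S5 = c(1, 1, 1), S6 = c(1, 1, 1))
  colnames(m) <- c("het", "v2", "v3")
  d <- dosage_from_matrix(m)
  afr <- allele_freq(d, panel, "AFR")
  expect_equal(afr$f[afr$variant_id == "het"], 0.5)           # all het
  # AFR uses S1..S3: dosages v2 = [2,2,0] -> 4/6; v3 = [2,2,2] -> 1
  expect_equal(afr$f[afr$variant_id == "v2"], 4 / 6)
  expect_equal(afr$n_chrom, rep(6L, 3))

  m2 <- rbind(a = 2, b = 2, c = 0, d = 0)
  colnames(m2) <- "v"
  rownames(m2) <- paste0("S", 1:4)
  p4 <- tibble::tibble(sample_id = paste0("S", 1:4), population = "YRI",
                       super_population = "AFR")
  expect_equal(allele_freq(dosage_from_matrix(m2), p4, "AFR")$f, 0.5)
  m3 <- m2; m3[, 1] <- c(2, 2, 2, 1)
  expect_equal(allele_freq(dosage_from_matrix(m3), p4, "AFR")$f, 0.875)

  # missing calls shrink n_chrom; all-missing variants are dropped with a log
  m4 <- cbind(v1 = c(2, NA, 0, 2), v2 = c(NA, NA, NA, NA))
  rownames(m4) <- paste0("S", 1:4)
  expect_message(fr <- allele_freq(dosage_from_matrix(m4), p4, "AFR"), "dropped")
  expect_equal(fr$variant_id, "v1")
  expect_equal(fr$n_chrom, 6L)
  expect_equal(fr$f, 4 / 6)
})

test_that("frequency estimates are within 3 binomial SE of simulator truth", {
  cfg <- sim_config(n_variants = 60, n_per_pop = 250, seed = 17)
  sim <- sim_dataset(cfg)
  ff <- allele_freq(sim$dosage, sim$panel, "FOC")
  merged <- dplyr::inner_join(ff, sim$truth, by = "variant_id")
  se <- sqrt(merged$f_focal * (1 - merged$f_focal) / merged$n_chrom)
  frac_in <- mean(abs(merged$f - merged$f_focal) <= 3 * se)
  expect_gt(frac_in, 0.95)  # 3 SE covers ~99.7%; allow a couple of excursions
})

test_that("sign test equals brute-force binomial tail enumeration", {
  st <- sign_test(freq_tbl(letters[1:10], c(rep(0.8, 8), 0.1, 0.1)),
                  freq_tbl(letters[1:10], c(rep(0.4, 8), 0.6, 0.6)))
  expect_equal(st$n_informative, 10L)
  expect_equal(st$n_higher, 8L)
  expect_equal(st$p_value, 56 / 1024)

  # exhaustive: every (n, k) with n <= 20 matches direct pmf summation
  for (n in 1:20) for (k in 0:n) {
    expect_equal(signburden:::binom_tail_p(k, n, "greater"),
                 binom_tail_oracle(k, n), tolerance = 1e-12)
  }
})

test_that("null-centred counts give p > 0.5 and ties are excluded", {
  st <- sign_test(freq_tbl(letters[1:10], c(rep(0.8, 5), rep(0.1, 5))),
                  freq_tbl(letters[1:10], c(rep(0.4, 5), rep(0.6, 5))))
  expect_equal(st$n_higher, 5L)
  expect_gt(st$p_value, 0.5)

  tied <- sign_test(freq_tbl(c("a", "b", "c"), c(0.5, 0.7, 0.2)),
                    freq_tbl(c("a", "b", "c"), c(0.5, 0.3, 0.4)))
  expect_equal(tied$n_ties, 1L)
  expect_equal(tied$n_informative, 2L)
  expect_equal(tied$n_higher, 1L)

  expect_warning(
    all_tied <- sign_test(freq_tbl("a", 0.5), freq_tbl("a", 0.5)),
    "no informative")
  expect_equal(all_tied$p_value, 1)
})

test_that("swapping focal and reference reflects the count", {
  set.seed(23)
  fa <- freq_tbl(sprintf("v%d", 1:30), runif(30))
  fb <- freq_tbl(sprintf("v%d", 1:30), runif(30))
  ab <- sign_test(fa, fb); ba <- sign_test(fb, fa)
  expect_equal(ba$n_higher, ab$n_informative - ab$n_higher)
  # two-sided p is symmetric and bounded by 1
  expect_equal(sign_test(fa, fb, "two.sided")$p_value,
               sign_test(fb, fa, "two.sided")$p_value)
  expect_lte(sign_test(fa, fb, "two.sided")$p_value, 1)
})

test_that("tidy and glance expose the sign-test fields", {
  st <- sign_test(freq_tbl(letters[1:10], c(rep(0.8, 8), 0.1, 0.1)),
                  freq_tbl(letters[1:10], c(rep(0.4, 8), 0.6, 0.6)))
  expect_equal(tidy(st)$statistic, 8L)
  expect_equal(tidy(st)$estimate, 0.8)
  expect_equal(glance(st)$p0, 0.5)
  expect_equal(glance(st)$p.value, st$p_value)
})

test_that("difference summaries count large differences with a strict cutoff", {
  ids <- c("a", "b", "c")
  same <- diff_summary(freq_tbl(ids, c(0.1, 0.5, 0.9)),
                       freq_tbl(ids, c(0.1, 0.5, 0.9)))
  expect_equal(same$min_abs_diff, 0)
  expect_equal(same$max_abs_diff, 0)
  expect_equal(same$n_large, 0L)

  ds <- diff_summary(freq_tbl(ids, c(0.5, 0.5, 0.5)),
                     freq_tbl(ids, c(0.4, 0.25, 0.2)))
  expect_equal(ds$min_abs_diff, 0.1)
  expect_equal(ds$max_abs_diff, 0.3)
  expect_equal(ds$n_large, 2L)
  expect_equal(ds$prop_large, 2 / 3)
  # strict '>': a difference exactly at the cutoff does not count
  at <- diff_summary(freq_tbl("a", 0.5), freq_tbl("a", 0.3))
  expect_equal(at$n_large, 0L)
})

test_that("the subset sign test restricts to the largest differences", {
  # threshold 0 reduces to the full sign test on non-tied variants
  set.seed(29)
  fa <- freq_tbl(sprintf("v%d", 1:25), runif(25))
  fb <- freq_tbl(sprintf("v%d", 1:25), runif(25))
  expect_equal(subset_sign_test(fa, fb, threshold = 0)$p_value,
               sign_test(fa, fb)$p_value)

  # constructed: exactly the 5 largest of 20 diffs exceed 0.2, 4 of them positive
  diffs <- c(seq(0.001, 0.015, length.out = 15), 0.3, 0.35, 0.4, 0.45, -0.5)
  base <- rep(0.5, 20)
  fa2 <- freq_tbl(sprintf("w%d", 1:20), base + diffs / 2)
  fb2 <- freq_tbl(sprintf("w%d", 1:20), base - diffs / 2)
  sst <- subset_sign_test(fa2, fb2, threshold = 0.2)
  expect_equal(sst$n_informative, 5L)
  expect_equal(sst$n_higher, 4L)
  expect_setequal(sst$variants, sprintf("w%d", 16:20))

  expect_warning(empty <- subset_sign_test(fa2, fb2, threshold = 0.9),
                 "threshold")
  expect_equal(empty$p_value, 1)
})

test_that("frequency tables round-trip through TSV", {
  f <- freq_tbl(c("a", "b"), c(0.25, 0.75), group = "AFR")
  path <- tempfile(fileext = ".tsv")
  write_freq_table(f, path)
  back <- read_freq_table(path)
  expect_equal(back$f, f$f)
  expect_equal(back$variant_id, f$variant_id)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tgroup\tf", "a\tX\t1.2"), bad)
  expect_error(read_freq_table(bad), "outside")
})
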