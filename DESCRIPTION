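Package: signburden
Title: Genetic Risk Score Burden and Binomial Sign Tests for Polygenic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds unweighted genetic risk scores (GRS) from GWAS-catalog
    risk variants and VCF genotypes or imputation dosages, harmonizing risk
    alleles to REF/ALT orientation with strand-flip handling, pruning variants
    to linkage-disequilibrium independence (pairwise genotype r-squared), and
    comparing score distributions between population groups. Tests for
    systematic between-population differences in risk-allele frequencies with
    an exact binomial (QTL) sign test, including large-frequency-difference
    subset analyses. Includes a Balding-Nichols F_ST drift simulator with an
    optional directional logit-scale selection shift and LD blocks, emitting
    catalog/VCF/panel files so the whole pipeline can be exercised without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
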