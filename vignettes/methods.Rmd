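---
title: "Methods: risk-allele burden scores and the binomial sign test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-allele burden scores and the binomial sign test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signburden)
```

This vignette documents the statistical model behind `signburden`, the
choices that were genuinely open when the package was designed, and what its
simulation-based validation does and does not establish.

## The question and the two statistics

Given a panel of risk variants for a trait (or a family of related traits)
and genotypes for two populations, we ask whether risk alleles are
*systematically* more frequent in one population — the signature expected if
selection, rather than drift, moved the trait's genetic architecture.

**Unweighted GRS.** The per-individual score is the plain sum of risk-allele
dosages over the panel, in units of risk alleles (0 to 2M for M variants).
Weighting by published effect sizes is deliberately not part of the core:
when the selected phenotype is unknown or unmeasured, disease effect sizes
estimated in modern cohorts are not the effects selection acted on, and an
unweighted count makes no proportionality assumption. A weighted score can
be built externally by scaling dosage columns before `compute_grs()`.

**Binomial sign test.** Under neutrality, whether a given risk allele drifts
to higher frequency in population A or B is a fair coin flip, independently
across LD-independent loci. With $n$ non-tied variants and $k$ of them more
frequent in the focal population, the one-sided evidence against neutrality
is the exact tail $P(K \ge k) = \sum_{j=k}^{n} \binom{n}{j} 2^{-n}$.
The assumptions that matter:

* *Independence across loci* — this is why LD pruning (r² < 0.2) and the
  HLA exclusion precede the test; correlated loci would count the same coin
  flip twice.
* *No ascertainment asymmetry* — the test assumes discovery of the variants
  did not favour alleles frequent in one of the two populations compared.
  This is a real limitation with GWAS panels discovered predominantly in
  European-ancestry cohorts; it biases *against* finding an excess in a
  non-European focal group, so a positive result is conservative in that
  direction, but the package cannot correct for it.
* Exact frequency ties are uninformative and are excluded, following
  classical sign-test practice; with continuous dosages ties are rare, with
  small-sample hard calls they are not.

The mean-GRS comparison uses Welch's unequal-variance two-sided *t*-test.
The two statistics are complementary: the *t*-test asks "is the average
burden higher?", which a few strongly differentiated loci can drive; the
sign test asks "do *most* loci lean the same way?", which is the polygenic
signature.

## Pipeline stages and their parameters

`run_pipeline()` executes the stages below; each is exported on its own.

| Parameter | Default | Units | Why |
|---|---|---|---|
| `p_threshold` | 5e-8 | p-value | conventional genome-wide significance |
| HLA window | chr6:25–35 Mb, half-open | GRCh37 bp | widely used extended-MHC bound; long-range LD breaks locus independence |
| `r2_threshold` | 0.2 | genotype r² | standard "quasi-independent" pruning level |
| `diff_threshold` | 0.2 | allele frequency | large-difference subset cutoff, strict `>` |
| `missing_policy` | `"rescale"` | — | keeps scores on the full-panel scale when marker availability differs between cohorts |
| `alternative` | `"greater"` | — | directional hypothesis: risk alleles more frequent in the focal group |

Notes on the less obvious ones:

* **Coordinates** are 1-based (VCF convention) and regions half-open
  `[start, end)`, so adjacent windows cannot double-count a position.
* **Allele harmonization.** Catalog risk/other alleles are matched to VCF
  REF/ALT exactly first, then by reverse complement (strand flip).
  Palindromic A/T and C/G pairs that match without flipping are *accepted*
  as plus-strand — reference datasets in the 1000 Genomes mould are
  plus-strand by construction — but flagged, since strand cannot be proven
  from the alleles alone; dropping them silently would quietly shrink the
  panel. Unresolvable variants are excluded and logged, never guessed.
* **Dosage source.** `DS` is preferred over `GT` when both are present
  (imputed datasets); `prefer = "GT"` forces hard calls. Missing genotypes
  stay missing — imputing zero would bias scores downward.
* **LD pruning** is greedy keep-first: variants are visited in genomic
  order (or by ascending association p-value with `order = "pvalue"`) and
  kept iff their r² with every already-kept variant on the same chromosome
  is below threshold. r² is the squared Pearson correlation of unphased
  dosages over pairwise-complete samples (composite LD) — phase-free, which
  is all dosage data can support. Cross-chromosome pairs are never pruned.
  Monomorphic variants have undefined r² and are treated as unlinked rather
  than silently removed. Greedy keep-first is not the only defensible
  order; it is deterministic, standard, and reproducible, which matters
  more here than optimality of the kept set.
* **Pruning is optional** (`prune = FALSE`) because published GRS SNP lists
  are typically already pruned, and because pruning a *pooled* two-population
  sample can remove unlinked variants whose correlation is induced by
  population structure rather than physical LD.
* **Missing-data rescaling**: a sample scored on `m_used` of `M` variants
  gets its sum multiplied by `M / m_used`. This is the policy that keeps a
  cohort genotyped on a subset of the panel comparable to one with complete
  data; `"raw"` is available when absolute counts are wanted.
* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile()` type 7) so summary tables are bit-reproducible.

Degenerate inputs are handled as values, not crashes: two constant
identical groups give t = 0, p = 1; a sign test with no informative
variants warns and returns p = 1; a sample with no non-missing variants is
excluded with a warning; rendering a report with an empty group summary
fails loudly rather than omitting the section.

## The simulator

`sim_config()` / `sim_dataset()` / `emit_dataset()` realize the neutral
null and a directional alternative:

1. Ancestral risk-allele frequency $p \sim$ Uniform(0.05, 0.95) by default
   — GWAS-ascertained risk variants are common, with no strong skew; a
   Beta option exists for other spectra.
2. Each population's frequency is a Balding–Nichols draw
   $f \sim \mathrm{Beta}\!\big(p(1-F)/F,\ (1-p)(1-F)/F\big)$ with
   $F = F_{ST}$: mean $p$, variance $F\,p(1-p)$. This is the standard
   F_ST-indexed drift null.
3. Selection is a fixed logit shift of the focal population's frequency,
   $\mathrm{logit}(f') = \mathrm{logit}(f) + \delta$ — the simplest
   alternative in which every risk allele tends the same way. δ = 0 is the
   neutral regime.
4. Frequencies are clamped to [0.01, 0.99] so no simulated variant is
   monomorphic in truth (configurable).
5. Genotypes are Binomial(2, f) per individual (Hardy–Weinberg).
   Optional LD blocks copy a seed variant's genotype column with
   per-entry redraw probability 1 − fidelity; block members share the
   seed's frequencies and chromosome, so the truth table remains exact and
   the induced correlation is physical-LD-like.

Defaults are the study conditions the validation targets: L = 147
variants, 300 samples per population, F_ST = 0.15 (a typical
continental-scale divergence). A fixed seed makes `emit_dataset()` output
byte-identical across runs.

**What the simulator does not emulate** — and therefore what passing tests
do not establish about real data: ascertainment bias in variant discovery;
admixed individuals and within-group structure; genotyping or imputation
error (the DS option adds only bounded formatting noise); realistic
recombination maps (LD blocks are exchangeable copies, not coalescent
haplotypes); and correlated drift across loci. The validation shows the
*machinery* is correct under its stated model, not that the model captures
every property of human cohort data.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: hand-
enumerated fixtures for parsing; an exhaustive 16-pairing enumeration for
allele orientation; the covariance-formula r² against the implementation;
brute-force binomial pmf summation against the sign-test tail for all
n ≤ 20; textbook Welch formulas; and a post-hoc checker that re-verifies
every pruning output (all kept same-chromosome pairs below threshold,
every removed variant with a kept culprit at or above it).

Distributional guarantees use the simulator at study scale: type-I error of
the sign test from 500 neutral replicates per F_ST level (the empirical
rejection rate at α = 0.05 is expected in [0.02, 0.07] — the exact test is
conservative because the Binomial(147, ½) tail is discrete), and power from
200 replicates per δ ∈ {0, 0.5, 1}, expected non-decreasing in δ and above
0.8 at δ = 1. These replicate counts keep the full suite to a couple of
minutes on one CPU while leaving the binomial Monte-Carlo error on a rate
estimate near ±0.02; they are the package's chosen problem sizes, and
`scripts/acceptance.R` re-runs the same computations from scratch with a
user-supplied seed.

## Known limitations

* The sign test treats frequency *estimates* as observations; with very
  small samples, estimation noise around equal frequencies inflates
  near-ties into coin flips symmetrically, which keeps the null calibrated
  but dilutes power.
* X-chromosome variants are scored as diploid in all samples; a proper
  treatment would need per-sample sex and hemizygous dosage handling.
* Multi-allelic VCF records at catalog SNPs are skipped with a log entry
  rather than decomposed; split them upstream (e.g. `bcftools norm -m-`)
  if they matter.
* Greedy pruning in a pooled structured sample conflates stratification
  with LD; prune within one population, or feed an already-pruned list.
* The large-difference cutoff is strict (`|Δf| > 0.2`); a boundary
  difference of exactly 0.2 is excluded. The choice between `>` and `≥`
  is a convention — it is configurable, and the package picks strict
  inequality consistently.
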