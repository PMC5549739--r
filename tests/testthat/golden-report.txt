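== GRS burden and polygenic sign-test report ==

-- stage funnel --
  catalog_rows     40
  genome_wide      40
  after_hla        40
  after_dedupe     40
  matched_in_vcf   40
  after_prune      40

-- GRS by population (sorted by median burden) --
group        n     mean    min    q25 median    q75    max
REF1        60    40.40   30.0   38.0   41.0   43.0   49.0
FOC1        60    51.60   44.0   50.0   51.5   53.2   57.0

-- GRS by super-population --
group        n     mean    min    q25 median    q75    max
REF         60    40.40   30.0   38.0   41.0   43.0   49.0
FOC         60    51.60   44.0   50.0   51.5   53.2   57.0

-- mean comparisons --
main: mean(FOC) - mean(REF) = 11.20 risk alleles
  Welch t = 18.52, df = 104.1, two-sided p = 1.03e-34

-- sign test --
  27 of 39 informative variants at higher risk-allele frequency in FOC (p0 = 1/2)
  exact binomial p (greater) = 0.01185
  |f diff| range: 0.000 to 0.708; 13 of 40 variants > 0.20
  large-difference subset: 11 of 13 higher in FOC, p = 0.01123
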