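# rburden

Autozygosity-aware recessive coding burden analysis for exome-sequenced
parent–offspring trio cohorts.

## What it does, and for whom

In rare-disease trio cohorts — especially those with ancestrally diverse or
consanguineous families — a recurring question is: *what fraction of
patients is explained by rare biallelic (autosomal recessive) coding
genotypes, and in which genes?* Answering it requires an expectation model
that accounts for autozygosity: children of related parents carry runs of
homozygosity (ROH) in which any rare recessive allele is automatically
homozygous, so their background rate of biallelic genotypes is elevated for
reasons that have nothing to do with disease.

`rburden` is for statistical geneticists running that analysis. For each
gene *g*, variant class pair *c* (LoF/LoF, LoF/functional,
functional/functional, plus a synonymous/synonymous control) and ancestry
stratum *p* it computes:

* **Expected counts** `E(b_cpg) = N_p * lambda_cpg` with

  `lambda_cpg = (1 - a_pg) f_cpg^2 + a_pg f_cpg`

  for within-class pairs, where `f_cpg` is the cumulative frequency of
  parental haplotypes carrying ≥ 1 rare variant of class *c* in gene *g*
  (estimated from unrelated, unaffected parents with transmission-based
  phasing of multi-heterozygotes) and `a_pg` is the proportion of probands
  whose ROH overlap the gene; and

  `lambda = (1 - a) * 2 f_LoF f_func (1 - f_LoF)`

  for LoF/functional compound heterozygotes.

* **Observed counts** by detecting homozygous-alternate genotypes and
  compound heterozygotes phased by transmission (≥ 1 heterozygous variant
  demonstrably inherited from each parent), after Mendelian filtering and
  most-severe deduplication per trio and gene.

* **Burden statistics**: one-sided Poisson enrichment tests, the
  attributable fraction `AF = (ΣO − ΣE)/N` with exact Poisson (Garwood)
  confidence intervals, pooled/federated estimates via a summary-exchange
  format that carries no genotypes, synonymous-null calibration of the ROH
  parameters, residual-risk stratification at F_ROH = 0.0156 (the
  second-cousin-offspring expectation), and per-gene tests via the
  sum-of-Poissons approximation with an exact sum-of-independent-binomials
  reference, Bonferroni (`0.05 / (4 × gene universe)`) and BH-FDR
  correction.

* **Synthetic cohorts**: a Mendelian-consistent generator of stratified
  consanguineous trio cohorts with controlled allele frequencies, per-gene
  autozygosity realized as ROH, an independent frequency panel, and
  injected causal burden with truth labels — so the whole pipeline is
  testable end-to-end without access to any patient data.

## Worked example

```r
library(rburden)

cfg <- simulation_config(seed = 7, theta = 0.05)   # inject 5% attributable fraction
cohort <- simulate_cohort(cfg)
pl <- run_burden_pipeline(cohort, freq_mode = "panel")
attributable_fraction(pl$observed, pl$expected, pl$n_probands)
```

```
<burden_result> O = 163, E = 35.960, N = 2500
  AF = 0.0508 (95% CI 0.0412 to 0.0616), one-sided Poisson P = 6.13e-54
```

The injected 5% is recovered (point estimate 5.1%, CI covering 0.05) on top
of the background expectation of ~36 damaging biallelic genotypes in 2,500
trios. Per-gene discovery on the same cohort:

```r
res <- gene_burden_test(pl$observed, pl$expected,
                        n_genes_universe = nrow(cohort$genes))
res[bonferroni_significant & min_p_per_gene][order(p_value)][
  1:3, .(gene, combo, O_total, E_total, p_value)]
```

```
     gene                  combo O_total    E_total      p_value
1:   G007 lof_lof+lof_functional      14 0.04553193 1.809512e-30
2:   G008 lof_lof+lof_functional      12 0.05542350 1.666385e-24
3:   G004 lof_lof+lof_functional      13 0.10051973 1.564802e-23
```

The injection targets the first ten genes; exactly those rise to the top
with observed counts far above the sub-0.2 expectations. The
`synonymous_null_check()` on the same run confirms the control class stays
null.

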