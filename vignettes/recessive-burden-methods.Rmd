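---
title: "Methods: autozygosity-aware recessive coding burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autozygosity-aware recessive coding burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rburden)
library(data.table)
```

## The problem

A child of consanguineous parents inherits long genomic segments that are
identical by descent from a shared ancestor — runs of homozygosity (ROH). Any
rare recessive allele falling inside such a segment is automatically
homozygous. In trio-sequenced rare-disease cohorts this means the expected
number of biallelic (two-hit) genotypes per gene depends not only on allele
frequencies but also on each ancestry group's level of autozygosity, and any
burden test that ignores this will misattribute autozygosity to pathology.

`rburden` estimates, for each gene `g`, variant class pair `c` and ancestry
stratum `p`:

* the **expected** number of probands with a biallelic genotype, from
  parental haplotype frequencies and ROH-based autozygosity, and
* the **observed** number, from trio genotypes by direct detection of
  homozygous-alternate and transmission-phased compound-heterozygous
  genotypes,

then compares the two: exome-wide (the *attributable fraction*, the estimated
share of probands explained by recessive coding causes) and per gene
(enrichment tests for gene discovery).

## The expectation model

Variants are grouped into three classes on the canonical transcript:
**LoF** (stop gained, frameshift, essential splice, stop lost, transcript
ablation — only at high predicted loss-of-function confidence), **functional**
(missense, in-frame indels, start lost, splice region, low-confidence LoF,
and synonymous variants with splice-disruption score ≥ 0.8) and a
**synonymous control** class (synonymous with splice score < 0.1). Synonymous
variants with intermediate splice scores (0.1–0.8) fit neither definition and
are excluded entirely rather than guessed at.

Let `f` be the cumulative frequency of parental haplotypes in stratum `p`
carrying at least one retained variant of class `c` in gene `g`, and `a` the
proportion of probands in `p` whose ROH overlap `g` (≥ 1 bp; the natural
reading of "overlapping"). The per-proband biallelic rate for a within-class
pair is a convex combination of the panmictic rate and the autozygous rate:

```
lambda = (1 - a) * f^2 + a * f
```

For the cross-class LoF/functional compound heterozygote:

```
lambda = (1 - a) * 2 * f_LoF * f_functional * (1 - f_LoF)
```

the `(1 - f_LoF)` guarding against haplotypes that carry both a LoF and a
functional variant (those genotypes are LoF/LoF). Expected counts are
`E = N_probands * lambda`, summed freely over genes, classes, strata and
cohorts because expectation is linear. `f^2` deliberately counts both
homozygous and in-trans configurations without distinguishing them, exactly
as the generative model implies.

`f = h / N_haps` is estimated from unrelated, unaffected parents only
(affected or related parents are flagged out by the caller): a parent
contributes 2 haplotypes for a homozygous-alternate genotype, 1 for a single
heterozygote, and for multiple heterozygotes in the same gene/class the
phase is read from transmission to the child — 1 haplotype if the variants
are in cis, 2 if demonstrably in trans, 1 if unclear (the conservative
choice). An independent frequency panel without offspring can be used
instead; there multi-heterozygote phase is always unclear.

## Observed biallelic genotypes

Trio genotypes are first Mendelian-filtered: a site is dropped if any member
is missing or the proband genotype is impossible under biallelic
transmission. Detection then reports, per trio and gene:

* homozygous-alternate genotypes (class pair `c/c`), and
* compound heterozygotes: the proband demonstrably inherited ≥ 1
  heterozygous variant of the relevant class from *each* parent (distinct
  variants).

A heterozygous variant's parental origin is unambiguous iff exactly one
parent can have contributed the allele (the other parent carries no
alternate, or one parent is homozygous). A variant of ambiguous origin never
establishes a side by itself but may pair with an unambiguous opposite-side
variant when a consistent phase assignment puts the two in trans. A useful
fact proved out by our enumeration oracle: once genotypes are
Mendelian-filtered, the consistency of assigning a child's heterozygous
variant to the maternal or paternal haplotype is purely local to that
variant (the untransmitted parental haplotype absorbs any residual alleles),
so this "exists a consistent phase" semantics is computable in closed form
from per-variant side flags. The test suite verifies equality with a
brute-force enumeration over all phase assignments for every
Mendelian-consistent trio with up to three variants in a gene.

If a trio has several damaging biallelic genotypes in one gene only the most
severe is counted (LoF/LoF > LoF/functional > functional/functional); the
synonymous control class is tabulated independently. A homozygous functional
genotype is functional/functional — a co-occurring heterozygous LoF does not
promote it to LoF/functional, since no LoF/functional haplotype pair exists.
The X chromosome is excluded throughout (autosomal recessive analysis).

## Burden statistics

* **Enrichment**: one-sided Poisson tail `P(X >= O | X ~ Poisson(E))` for
  damaging classes; two-sided (doubled smaller tail, capped at 1) for the
  synonymous control, where deficits are equally diagnostic of
  miscalibration. The two-sided construction is the common doubling rule;
  the doubling convention matters little at the calibration stage where
  P values are compared, not thresholded.
* **Attributable fraction**: `AF = (sum O - sum E) / N` over the three
  damaging class pairs; pooling across strata and cohorts sums numerators
  and denominators. The 95% CI applies the exact Poisson (Garwood) interval
  to the summed observed count and transforms it to
  `((O_lo - E)/N, (O_hi - E)/N)`. This is deterministic and consistent with
  the Poisson testing framework; a published interval computed by another
  method (e.g. bootstrap over probands) need not match numerically.
* **Calibration**: when ROH are callable under several LD-thinning
  parameters, the candidate autozygosity per stratum is chosen to maximize
  the two-sided synonymous P value (observed closest to expected under the
  control class) and then reused for all damaging classes.
* **Subgroup comparison**: two-sided unpooled z-test for a difference in
  proportions, treating `AF * N` excess cases out of `N`. Whether to pool
  variances is ambiguous in common usage; the unpooled form is implemented.
* **Residual risk**: among undiagnosed probands without a damaging biallelic
  genotype in a known disease gene, the AF restricted to off-list genes is
  reported separately below and above F_ROH = 0.0156 — the expected
  inbreeding coefficient for offspring of second cousins, `4^-(k+1)` at
  k = 2 by pedigree path counting.

## Per-gene tests

Per-stratum counts are Poisson with rates `E_p`, so the gene total is
Poisson with rate `sum(E_p)`: the sum-of-Poissons test. The exact reference
— the tail of a sum of independent `Binomial(N_p, lambda_p)` — is also
implemented by dynamic-programming convolution of the per-stratum PMFs
truncated at the observed total, with overflow mass accumulated directly
into the tail (numerically exact for small tails). The exact test guards
its work budget (default 1e7 PMF cells) and directs large instances to the
Poisson approximation, which is why the approximation exists at all. At
rates ≤ 1e-3 the two agree within 5% relative error (verified over random
instances).

Four non-independent combinations are tested per gene: LoF/LoF; LoF/LoF +
LoF/functional; functional/functional; all three damaging pairs. Bonferroni
uses `alpha / (4 * G_universe)` with the configured gene universe (which may
exceed the genes that have any passing variant — both counts are reported).
BH-FDR is computed over the concatenated vector of all four tests for every
tested gene; a per-gene min-P mode is available but off by default, and the
two can order genes differently when one gene's four P values are highly
correlated. Ties between combos at the per-gene minimum go to the
earlier-listed combination.

## The synthetic cohort generator

No individual-level data ship with the package; every end-to-end claim is
validated on cohorts from `simulate_cohort()`, which generates the exact
model the expectation formulas describe:

* Each gene has a variant pool (default per gene: 2 LoF at per-haplotype
  frequency 0.001, 3 functional and 3 synonymous at 0.003), giving
  cumulative class frequencies of ~0.2% and ~0.9% — the scale expected
  after restricting to variants at MAF ≤ 0.005.
* Per gene and trio, with probability `a_gene` the trio is autozygous
  there: one population haplotype is planted in both parents and
  transmitted by both, and an ROH interval covering the gene is emitted.
  Otherwise each parent transmits one of two independent haplotypes.
  Children are Mendelian-consistent by construction.
* The toy genome gives each gene a 1 Mb block; an autozygous trio's ROH
  covers the block, so a proband's F_ROH is the fraction of genes
  autozygous and a stratum's mean F_ROH equals its `a_gene`.
* The default conditions are a large, low-autozygosity stratum (2,000
  trios, `a_gene` = 0.001, as in a large European-ancestry group) and a
  smaller consanguineous stratum (500 trios, `a_gene` = 0.05, as in groups
  with customary cousin marriage). These were fixed once as representative
  study conditions.
* `inject_causal()` overwrites the genotypes of `round(theta * n)` trios
  with a forced damaging biallelic genotype (homozygous LoF or a
  LoF + functional compound het with one variant per parent) in a target
  gene, keeping the variant pool fixed and labelling truth. A configurable
  fraction of causal variants is flagged ClinVar P/LP and of causal
  probands marked diagnosed, so the ClinVar-mask and diagnosed-subset
  analyses have ground truth too.

What the simulator does **not** emulate: linkage between genes, realistic
recombination or demography, sequencing error, genotype missingness beyond
what the caller introduces, or allele-frequency misspecification between
panel and cohort. Passing tests therefore demonstrate the statistical
machinery is faithful to its model, not that the model captures every
artefact of real exome data — which is exactly what the synonymous control
class is for in a real analysis.

Frequencies can be estimated from the trio parents themselves (the design
used on real cohorts) or from an independent panel. The panel mode is the
unbiased choice for parameter-recovery experiments, because injection
overwrites trio-parent genotypes and would otherwise leak the injected
alleles into the frequency estimate and inflate the expectation; with
`theta = 0.15` in 5,000 trios the leakage is worth about half a percentage
point of attributable fraction, which is why recovery runs use the panel.

## Numerical and degenerate-input choices

* `E = 0` with `O > 0` returns `p = 0` with a loud warning rather than an
  error, so one degenerate gene cannot block an exome-wide sum.
* Strata with no eligible parents are excluded from frequency estimation
  (`n_haps = 0` is an error, not a silent zero).
* Missing autozygosity for a stratum defaults to `a = 0` with a warning —
  conservative for enrichment, since it can only lower the expectation.
* Local rarity bound inclusive (≤ 0.005), reference bound exclusive
  (< 0.005), reference homozygote count must be zero: the asymmetry is
  intentional and matches how the filters are conventionally stated.
  Local strata with fewer than 150 unrelated, unaffected parents are
  non-binding for rarity.
* A missense deleteriousness hook (`functional_extra_filter`) exists but is
  off by default; it is a placeholder for cohort-specific filters, not a
  recommendation.
* Merging cohort summaries combines mean F_ROH as the proband-weighted
  mean, keeping merges associative and commutative.

## Problem sizes used in the shipped validation

The package's own test and acceptance runs use: a 5 × 5 (f, a) grid at 1e5
virtual probands per cell for the simulator-vs-formula oracle; 50 replicate
cohorts of 5,000 trios (40 genes, `a_gene` = 0.03, panel of 5,000 parents)
per injected theta in {0.01, 0.05, 0.15} for parameter recovery (observed
|bias| < 0.005); 100 random small-rate instances for exact-vs-approximate
gene-test agreement; the exhaustive ≤ 3-variant phase-oracle sweep; and 100
default-condition null cohorts for synonymous calibration. These sizes were
chosen to give Monte-Carlo error comfortably below each assertion's
tolerance while remaining a routine desktop run.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 7, theta = 0.05)
cohort <- simulate_cohort(cfg)
pl <- run_burden_pipeline(cohort, freq_mode = "panel")
attributable_fraction(pl$observed, pl$expected, pl$n_probands)
gene_burden_test(pl$observed, pl$expected,
                 n_genes_universe = nrow(cohort$genes))
```

## Known limitations

* The attributable fraction assumes every excess biallelic genotype fully
  explains one proband (complete penetrance, monogenic architecture).
* Small strata overestimate `f`, deflating the synonymous P value and
  biasing AF downward — the motivation for the binding-stratum rule and the
  synonymous calibration step.
* Compound-het detection requires demonstrable transmission; genotypes whose
  phase is genuinely unresolvable from a trio are not counted, a
  conservative miss that is quadratic in class frequency and negligible at
  rare-variant frequencies.
* The exact gene test is exponential-free but still quadratic in the
  observed total; genes with large totals use the Poisson approximation by
  design.
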