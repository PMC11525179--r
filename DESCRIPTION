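Package: rburden
Title: Autozygosity-Aware Recessive Coding Burden Analysis in Trio Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contribution of rare autosomal-recessive coding
    variants to disease in exome-sequenced parent-offspring trio cohorts.
    Implements autozygosity-aware expected counts of rare biallelic genotypes
    per gene and ancestry stratum, detection of observed biallelic genotypes
    (homozygous-alternate and transmission-phased compound heterozygotes),
    attributable-fraction estimation with exact Poisson confidence intervals,
    exome-wide and per-gene enrichment tests (sum-of-Poissons approximation
    and the exact sum-of-independent-binomials tail), multiple-testing
    correction, and a Mendelian-consistent synthetic consanguineous trio
    cohort generator with injected causal burden for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
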