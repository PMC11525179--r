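# Rate formulas, autozygosity, frequency estimation and the expectation table.

test_that("within-class biallelic rate follows (1-a)f^2 + af", {
  expect_equal(lambda_biallelic(0, 0.3), 0)
  expect_equal(lambda_biallelic(0.01, 0), 1e-4)
  expect_equal(lambda_biallelic(0.01, 1), 0.01)
  expect_equal(lambda_biallelic(0.02, 0.05), 0.95 * 4e-4 + 0.05 * 0.02)
  expect_equal(lambda_biallelic(0.02, 0.05), 1.38e-3)
})

test_that("LoF/functional compound-het rate follows (1-a)2 f_l f_f (1-f_l)", {
  expect_equal(lambda_comphet_lof_functional(0, 0.05, 0.2), 0)
  expect_equal(lambda_comphet_lof_functional(0.01, 0.05, 1), 0)
  expect_equal(lambda_comphet_lof_functional(0.01, 0.05, 0),
               2 * 0.01 * 0.05 * 0.99)
  expect_equal(lambda_comphet_lof_functional(0.01, 0.05, 0), 9.9e-4)
})

test_that("rates are monotone in autozygosity and bounded by f^2 and f", {
  fs <- seq(0, 1, by = 0.1)
  as_ <- seq(0, 1, by = 0.1)
  for (f in fs) {
    lam <- lambda_biallelic(f, as_)
    expect_true(all(diff(lam) >= -1e-15), label = sprintf("monotone at f=%g", f))
    expect_true(all(lam >= f^2 - 1e-15 & lam <= f + 1e-15),
                label = sprintf("bounds at f=%g", f))
  }
})

test_that("gene autozygosity is the proportion of probands with ROH overlap", {
  meta <- data.table::data.table(
    trio_id = sprintf("T%02d", 1:10), stratum = "SAS",
    cohort = "SIM", diagnosed = FALSE, sex = "F"
  )
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
  genes$name <- "G1"
  # three probands overlap the gene (one via a 1 bp overlap), one does not
  roh <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1500, 2000, 5000), c(1200, 1600, 2100, 6000))
  )
  roh$name <- c("T01", "T02", "T03", "T04")
  a <- gene_autozygosity(roh, genes, meta)
  expect_equal(a[gene == "G1" & stratum == "SAS"]$a, 0.3)

  # no ROH at all: empty (a = 0 everywhere)
  empty <- GenomicRanges::GRanges()
  empty$name <- character()
  expect_equal(nrow(gene_autozygosity(empty, genes, meta)), 0)
  expect_error(gene_autozygosity(roh, genes, meta[0]), "no probands")
})

test_that("per-proband F_ROH merges intervals over the genome length", {
  meta <- data.table::data.table(trio_id = c("T1", "T2"))
  roh <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 51, 201), c(100, 150, 300))
  )
  roh$name <- c("T1", "T1", "T1")  # overlapping intervals merge: 150 + 100 bp
  fr <- froh_per_proband(roh, meta, genome_length = 1000)
  expect_equal(fr[trio_id == "T1"]$froh, 0.25)
  expect_equal(fr[trio_id == "T2"]$froh, 0)
})

test_that("parental haplotype frequencies count hom, het and trans correctly", {
  v <- make_test_variants(c("LoF", "LoF", "functional"))
  # mother of T1: hom LoF at v1 -> 2 LoF haplotypes
  # mother of T2: two het LoFs in trans (v1 transmitted, v2 not) -> 2
  # father of T2: single functional het -> 1
  trios <- data.table::data.table(
    trio_id = c("T1", "T2", "T2", "T2"),
    variant_id = v$variant_id[c(1, 1, 2, 3)],
    gt_proband = c(1L, 1L, 0L, 1L),
    gt_mother = c(2L, 1L, 1L, 0L),
    gt_father = c(0L, 0L, 0L, 1L)
  )
  meta <- data.table::data.table(
    trio_id = c("T1", "T2"), stratum = "EUR", cohort = "SIM",
    diagnosed = FALSE, sex = "F",
    mother_eligible = TRUE, father_eligible = TRUE
  )
  fr <- haplotype_frequencies(trios, v, meta)
  n_haps <- 2L * 4L  # 4 eligible parents
  expect_equal(fr[class == "LoF"]$h, 4L)  # 2 (hom) + 2 (trans)
  expect_equal(fr[class == "functional"]$h, 1L)
  expect_equal(fr[class == "LoF"]$f, 4 / n_haps)

  # an ineligible (affected/related) parent does not contribute
  meta2 <- data.table::copy(meta)[trio_id == "T1", mother_eligible := FALSE]
  fr2 <- haplotype_frequencies(trios, v, meta2)
  expect_equal(fr2[class == "LoF"]$h, 2L)
  expect_equal(unname(attr(fr2, "n_haps_per_stratum")["EUR"]), 6L)
})

test_that("panel frequencies treat multi-het phase as unclear", {
  v <- make_test_variants(c("LoF", "LoF"))
  panel <- data.table::data.table(
    parent_id = c("P1", "P1", "P2"),
    variant_id = v$variant_id[c(1, 2, 1)],
    gt = c(1L, 1L, 2L)
  )
  pm <- data.table::data.table(parent_id = c("P1", "P2", "P3"), stratum = "EUR")
  fr <- panel_frequencies(panel, v, pm)
  expect_equal(fr[class == "LoF"]$h, 3L)  # 1 (unclear pair) + 2 (hom)
  expect_equal(fr[class == "LoF"]$n_haps, 6L)
})

test_that("expectation table assembles E = N * lambda per class pair", {
  freqs <- data.table::data.table(
    gene = "G1", class = "synonymous_control", stratum = "EUR",
    h = 10L, n_haps = 1000L, f = 0.01
  )
  auto <- data.table::data.table(stratum = character(), gene = character(),
                                 a = numeric())
  expect_warning(
    et <- expectation_table(freqs, auto, c(EUR = 1000L)),
    "assuming a = 0"
  )
  expect_equal(et[class_pair == "synonymous_synonymous"]$E, 0.1)
  expect_equal(et[class_pair == "lof_lof"]$E, 0)
  expect_equal(nrow(et), 4)  # one gene, one stratum, four class pairs

  # a = 1 reduces the rate to f: E = N * f
  auto2 <- data.table::data.table(stratum = "EUR", gene = "G1", a = 1)
  et2 <- expectation_table(freqs, auto2, c(EUR = 100L))
  expect_equal(et2[class_pair == "synonymous_synonymous"]$E, 1)
})

test_that("expectation matches Monte-Carlo genotype simulation", {
  # draw child haplotype carriage directly under the generative model at
  # random (f, a) pairs and compare to the closed-form rate
  set.seed(20240901)
  n <- 200000
  for (i in 1:6) {
    f <- runif(1, 0.005, 0.08)
    a <- runif(1, 0, 0.6)
    auto <- runif(n) < a
    hap1 <- runif(n) < f
    hap2 <- ifelse(auto, hap1, runif(n) < f)
    rate <- mean(hap1 & hap2)
    lam <- lambda_biallelic(f, a)
    se <- sqrt(lam * (1 - lam) / n)
    expect_lt(abs(rate - lam), 3 * se + 1e-12,
              label = sprintf("f=%.3f a=%.2f", f, a))
  }
})
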