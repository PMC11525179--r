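# Per-gene enrichment: exact sum-of-binomials tail, sum-of-Poissons
# approximation, class-pair combinations and multiple-testing correction.

test_that("single-stratum exact test is the binomial survival function", {
  for (o in 1:4) {
    got <- gene_test_exact(100L, 0.01, o)
    want <- pbinom(o - 1, 100, 0.01, lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_equal(gene_test_exact(c(10L, 20L), c(0.1, 0.2), 0), 1)
})

test_that("two-stratum exact tail matches full joint enumeration", {
  n <- c(2L, 3L); lam <- c(0.1, 0.2)
  for (o_total in 0:5) {
    want <- 0
    for (x1 in 0:2) for (x2 in 0:3) {
      if (x1 + x2 >= o_total)
        want <- want + dbinom(x1, 2, 0.1) * dbinom(x2, 3, 0.2)
    }
    expect_equal(gene_test_exact(n, lam, o_total), want, tolerance = 1e-12,
                 label = sprintf("o_total=%d", o_total))
  }
})

test_that("exact tail converges to the sum-of-Poissons tail for small rates", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(500:5000, 3)
    lam <- runif(3, 1e-6, 1e-4)
    o <- sample(1:4, 1)
    p_exact <- gene_test_exact(n, lam, o)
    p_pois <- gene_test_poisson(rep(0, 3) + o * c(1, 0, 0), n * lam)
    expect_equal(p_exact, p_pois, tolerance = 5e-3,
                 label = sprintf("n=%s lam sum=%.2g o=%d",
                                 paste(n, collapse = ","), sum(n * lam), o))
  }
})

test_that("the exact test refuses work beyond its budget", {
  expect_error(gene_test_exact(rep(1000L, 10), rep(0.1, 10), 5000L,
                               max_cells = 1e6),
               "work budget")
})

test_that("combos sum observed and expected over their constituent pairs", {
  obs <- data.table::data.table(
    gene = "G1", class_pair = c("lof_lof", "lof_functional"),
    stratum = "EUR", O = c(1L, 1L)
  )
  exp_ <- data.table::data.table(
    gene = "G1",
    class_pair = c("lof_lof", "lof_functional", "functional_functional"),
    stratum = "EUR", E = c(0.1, 0.2, 0.3)
  )
  cb <- build_combos(obs, exp_)
  expect_equal(nrow(cb), 4)
  expect_equal(cb[combo == "lof_lof"]$O_total, 1L)
  expect_equal(cb[combo == "lof_lof+lof_functional"]$O_total, 2L)
  expect_equal(cb[combo == "lof_lof+lof_functional+functional_functional"]$O_total, 2L)
  expect_equal(cb[combo == "lof_lof+lof_functional+functional_functional"]$E_total,
               0.6)
  # E additivity
  expect_equal(
    cb[combo == "lof_lof+lof_functional+functional_functional"]$E_total,
    sum(cb[combo %in% c("lof_lof", "functional_functional")]$E_total) +
      exp_[class_pair == "lof_functional"]$E
  )
  # all-zero observed gives four zero-O combos
  cb0 <- build_combos(obs[0], exp_)
  expect_equal(cb0$O_total, rep(0L, 4))
})

test_that("per-gene Poisson test sums counts across strata", {
  o <- c(1L, 1L, 0L)
  e <- c(0.001, 0.002, 0.001)
  expect_equal(gene_test_poisson(o, e), poisson_tail_one_sided(2, 0.004))
  expect_equal(gene_test_poisson(c(0L, 0L), c(1, 2)), 1)
})

test_that("BH matches brute-force step-up and Bonferroni uses the universe", {
  p <- c(0.001, 0.02, 0.04, 0.9, 1e-8, 0.3, 0.05, 0.6, 0.011, 0.25, 1, 0.07)
  res <- data.table::data.table(
    gene = rep(sprintf("G%d", 1:3), each = 4),
    combo = rep(rburden:::GENE_COMBOS, 3),
    p_value = p
  )
  mt <- multiple_testing(res, n_genes_universe = 3)
  expect_equal(mt$q_value, oracle_bh(p))
  expect_equal(attr(mt, "bonferroni_threshold"), 0.05 / 12)
  expect_identical(mt$bonferroni_significant, p < 0.05 / 12)
  # min-p markers: one per gene, at its smallest p
  expect_equal(sum(mt$min_p_per_gene), 3)
  expect_true(all(mt[min_p_per_gene == TRUE, p_value] ==
                    tapply(p, rep(1:3, each = 4), min)))

  # all p = 1: nothing significant
  res1 <- data.table::copy(res)[, p_value := 1]
  mt1 <- multiple_testing(res1, n_genes_universe = 3)
  expect_false(any(mt1$bonferroni_significant))

  # the Bonferroni denominator reflects the configured universe, not the
  # tested genes
  mt_u <- multiple_testing(res, n_genes_universe = 17320)
  expect_equal(attr(mt_u, "bonferroni_threshold"), 0.05 / (17320 * 4))
})

test_that("taking min-p over combos never loses a Bonferroni hit", {
  set.seed(8)
  for (i in 1:20) {
    res <- data.table::data.table(
      gene = rep(sprintf("G%d", 1:5), each = 4),
      combo = rep(rburden:::GENE_COMBOS, 5),
      p_value = 10^runif(20, -9, 0)
    )
    mt <- multiple_testing(res, n_genes_universe = 5)
    hit_any <- mt[, .(hit = any(bonferroni_significant)), by = gene]
    hit_minp <- mt[min_p_per_gene == TRUE,
                   .(gene, hit2 = bonferroni_significant)]
    j <- merge(hit_any, hit_minp, by = "gene")
    expect_identical(j$hit, j$hit2)
  }
})

test_that("synonymous null check flags an injected synonymous excess", {
  genes <- sprintf("G%02d", 1:30)
  exp_ <- data.table::data.table(
    gene = genes, class_pair = "synonymous_synonymous", stratum = "EUR",
    E = 0.5
  )
  set.seed(9)
  obs <- data.table::data.table(
    gene = genes, class_pair = "synonymous_synonymous", stratum = "EUR",
    O = rpois(30, 0.5)
  )
  obs[gene == "G07", O := 15L]  # constructed excess
  chk <- synonymous_null_check(obs, exp_)
  expect_equal(chk$per_gene[which.min(p_value)]$gene, "G07")
  # all-zero observed and expected genes give p = 1
  chk0 <- synonymous_null_check(obs[0], exp_[, .(gene, class_pair, stratum, E = 0)])
  expect_true(all(chk0$per_gene$p_value == 1))
})

test_that("gene_burden_test integrates combos, tests and correction", {
  obs <- data.table::data.table(
    gene = c("G1", "G1"), class_pair = c("lof_lof", "lof_functional"),
    stratum = c("EUR", "SAS"), O = c(2L, 1L)
  )
  exp_ <- data.table::data.table(
    gene = rep(c("G1", "G2"), each = 3),
    class_pair = rep(c("lof_lof", "lof_functional", "functional_functional"), 2),
    stratum = "EUR", E = c(0.001, 0.002, 0.01, 0.001, 0.001, 0.001)
  )
  res <- gene_burden_test(obs, exp_, n_genes_universe = 17320)
  expect_equal(nrow(res), 8)
  g1 <- res[gene == "G1" & combo == "lof_lof+lof_functional"]
  expect_equal(g1$p_value, poisson_tail_one_sided(3, 0.003))
  expect_true(g1$bonferroni_significant)
  expect_true(all(res[gene == "G2"]$p_value == 1))
})
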