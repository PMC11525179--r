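# Exome-wide burden statistics: Poisson tails, attributable fraction,
# calibration, comparisons, residual risk and diagnostic-yield arithmetic.

test_that("one-sided Poisson tail matches high-precision series summation", {
  set.seed(3)
  for (i in 1:50) {
    o <- sample(0:20, 1)
    e <- runif(1, 1e-4, 10)
    got <- poisson_tail_one_sided(o, e)
    want <- oracle_poisson_tail(o, e)
    expect_equal(got, want, tolerance = 1e-10, label = sprintf("O=%d E=%g", o, e))
  }
  expect_equal(poisson_tail_one_sided(0, 5), 1)
  expect_warning(p0 <- poisson_tail_one_sided(3, 0), "expected = 0")
  expect_equal(p0, 0)
})

test_that("two-sided Poisson tail doubles the smaller tail with a cap", {
  expect_equal(poisson_tail_two_sided(0, 10), 2 * exp(-10))
  expect_gt(poisson_tail_two_sided(100, 100), 0.9)
  set.seed(4)
  for (i in 1:30) {
    o <- sample(0:30, 1); e <- runif(1, 0.01, 15)
    p <- poisson_tail_two_sided(o, e)
    expect_lte(p, 1)
    expect_gt(p, 0)
    expect_equal(p, min(1, 2 * min(ppois(o, e),
                                   ppois(o - 1, e, lower.tail = FALSE))))
  }
})

make_oe <- function(O_vals, E_vals, strata = "EUR", gene = "G1") {
  list(
    observed = data.table::data.table(
      gene = gene, class_pair = rep(DAMAGING <- c("lof_lof", "lof_functional",
                                                  "functional_functional"),
                                    length.out = length(O_vals)),
      stratum = strata, O = O_vals
    ),
    expected = data.table::data.table(
      gene = gene, class_pair = rep(c("lof_lof", "lof_functional",
                                      "functional_functional"),
                                    length.out = length(E_vals)),
      stratum = strata, E = E_vals
    )
  )
}

test_that("attributable fraction is (sum O - sum E) / N with a sane CI", {
  oe <- make_oe(c(100L, 30L, 20L), c(50, 25, 25))
  r <- attributable_fraction(oe$observed, oe$expected, c(EUR = 1000L))
  expect_equal(r$af, (150 - 100) / 1000)
  expect_equal(r$af, 0.05)
  expect_true(r$af >= r$af_ci[1] && r$af <= r$af_ci[2])
  expect_true(r$af_ci[1] >= -r$E / r$N && r$af_ci[2] <= 1.2)

  # O = E gives AF = 0
  oe0 <- make_oe(c(50L, 0L, 0L), c(50, 0, 0))
  expect_equal(attributable_fraction(oe0$observed, oe0$expected,
                                     c(EUR = 1000L))$af, 0)
})

test_that("pooling strata sums numerators and denominators", {
  obs <- data.table::data.table(
    gene = "G1", class_pair = "lof_lof",
    stratum = c("A", "B"), O = c(15L, 45L)
  )
  exp_ <- data.table::data.table(
    gene = "G1", class_pair = "lof_lof",
    stratum = c("A", "B"), E = c(5, 45)
  )
  r <- attributable_fraction(obs, exp_, c(A = 100L, B = 900L))
  expect_equal(r$af, (60 - 50) / 1000)
  expect_equal(r$af, 0.01)
  # scope restriction to one stratum
  rA <- attributable_fraction(obs, exp_, c(A = 100L, B = 900L), strata = "A")
  expect_equal(rA$af, 0.1)
})

test_that("autozygosity calibration picks the candidate with the largest synonymous P", {
  obs <- data.table::data.table(gene = "G1",
                                class_pair = "synonymous_synonymous",
                                stratum = "EUR", O = 10L)
  cand <- list(
    thin0.1 = data.table::data.table(gene = "G1",
                                     class_pair = "synonymous_synonymous",
                                     stratum = "EUR", E = 3),
    thin0.5 = data.table::data.table(gene = "G1",
                                     class_pair = "synonymous_synonymous",
                                     stratum = "EUR", E = 10)
  )
  cal <- calibrate_autozygosity(cand, obs, c(EUR = 100L))
  expect_equal(cal$choice$candidate, "thin0.5")
  expect_equal(cal$expected$E, 10)

  # a single candidate is returned as-is; ties go to the first listed
  cal1 <- calibrate_autozygosity(cand[1], obs, c(EUR = 100L))
  expect_equal(cal1$choice$candidate, "thin0.1")
  tie <- calibrate_autozygosity(list(a = cand[[2]], b = cand[[2]]), obs,
                                c(EUR = 100L))
  expect_equal(tie$choice$candidate, "a")
})

test_that("attributable fractions compare by a two-proportion z-test", {
  r1 <- list(af = 0.069, N = 9000L)
  r2 <- list(af = 0.026, N = 16000L)
  cmp <- compare_af(r1, r2)
  # closed-form z
  se <- sqrt(0.069 * 0.931 / 9000 + 0.026 * 0.974 / 16000)
  expect_equal(cmp$z, (0.069 - 0.026) / se)
  expect_lt(cmp$p_value, 1e-10)
  # identical inputs: p = 1; symmetric in its arguments
  expect_equal(compare_af(r1, r1)$p_value, 1)
  expect_equal(compare_af(r1, r2)$p_value, compare_af(r2, r1)$p_value)
})

test_that("AF-autozygosity correlation behaves at the limits", {
  froh <- c(0.0005, 0.001, 0.004, 0.01, 0.02, 0.03, 0.05)
  af <- 2 * froh
  r <- correlate_af_autozygosity(af, froh)
  expect_equal(r$r, 1)
  set.seed(5)
  af_noise <- 2 * froh + rnorm(7, sd = 1e-5)
  expect_gt(correlate_af_autozygosity(af_noise, froh)$r, 0.999)
  # permuted pairings decorrelate on average
  mean_abs_r <- mean(replicate(200, {
    abs(correlate_af_autozygosity(sample(af_noise), froh)$r)
  }))
  expect_lt(mean_abs_r, 0.6)
  expect_error(correlate_af_autozygosity(c(1, 1, 1), froh[1:3]), "constant")
  expect_error(correlate_af_autozygosity(af[1:2], froh[1:2]), "at least 3")
})

test_that("residual risk restricts to off-list genes per autozygosity group", {
  known <- c("G1", "G2")
  obs <- list(
    low = data.table::data.table(gene = c("G1", "G5"), class_pair = "lof_lof",
                                 stratum = "EUR", O = c(5L, 10L)),
    high = data.table::data.table(gene = c("G2", "G5"), class_pair = "lof_lof",
                                  stratum = "EUR", O = c(3L, 30L))
  )
  exp_ <- list(
    low = data.table::data.table(gene = c("G1", "G5"), class_pair = "lof_lof",
                                 stratum = "EUR", E = c(1, 10)),
    high = data.table::data.table(gene = c("G2", "G5"), class_pair = "lof_lof",
                                  stratum = "EUR", E = c(1, 10))
  )
  n <- list(low = c(EUR = 1000L), high = c(EUR = 400L))
  rr <- residual_risk(obs, exp_, n, known_genes = known)
  expect_equal(rr$froh_threshold, 0.0156)
  # the known-gene counts are excluded: low has no excess, high does
  expect_equal(rr$low$af, 0)
  expect_equal(rr$high$af, 20 / 400)
  # an empty group is reported as not estimable
  rr2 <- residual_risk(obs["high"], exp_["high"],
                       list(high = c(EUR = 400L)), known)
  expect_null(rr2$low)
})

test_that("cousin-offspring inbreeding follows 4^-(k+1)", {
  expect_equal(cousin_offspring_froh(1), 0.0625)
  expect_equal(cousin_offspring_froh(2), 0.015625)
  ks <- 1:6
  expect_true(all(diff(cousin_offspring_froh(ks)) < 0))
  expect_error(cousin_offspring_froh(0), "integer >= 1")
})

test_that("diagnostic-yield arithmetic converts AF into missed diagnoses", {
  y0 <- diagnostic_yield(confirmed = 100, af = 0, n_undiagnosed = 5000)
  expect_equal(y0$additional, 0)
  expect_equal(y0$missing_fraction, 0)
  y <- diagnostic_yield(confirmed = 200, af = 0.02, n_undiagnosed = 3000,
                        reported_candidates = 400)
  expect_equal(y$additional, 60)
  expect_equal(y$missing_fraction, 60 / 260)
  expect_equal(y$pathogenic_fraction, 0.02 * 3000 / 400)
  expect_error(diagnostic_yield(1, 0.1, 10, reported_candidates = 0),
               "positive")
})

test_that("AF confidence intervals cover an injected Poisson excess", {
  # Poisson draws around a known background expectation plus theta * N
  # excess cases: the Garwood-transformed interval should cover theta at
  # roughly its nominal rate
  set.seed(6)
  theta <- 0.04
  N <- 2000L
  E_bg <- 30
  cover <- replicate(200, {
    O <- rpois(1, E_bg + theta * N)
    obs <- data.table::data.table(gene = "G1", class_pair = "lof_lof",
                                  stratum = "S", O = O)
    exp_ <- data.table::data.table(gene = "G1", class_pair = "lof_lof",
                                   stratum = "S", E = E_bg)
    ci <- attributable_fraction(obs, exp_, c(S = N))$af_ci
    ci[1] <= theta && theta <= ci[2]
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
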