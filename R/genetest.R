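# Per-gene enrichment tests across ancestry strata: the sum-of-Poissons
# approximation, the exact sum-of-independent-binomials tail, the four
# damaging class-pair combinations, and multiple-testing correction.

GENE_COMBOS <- c(
  "lof_lof",
  "lof_lof+lof_functional",
  "functional_functional",
  "lof_lof+lof_functional+functional_functional"
)

combo_parts <- function(combo) strsplit(combo, "+", fixed = TRUE)[[1]]

#' Per-gene sum-of-Poissons enrichment test
#'
#' The per-stratum counts of biallelic genotypes in a gene are modelled as
#' independent Poisson variables with rates E_p; their total is then Poisson
#' with rate sum(E_p). The test sums observed and expected counts across
#' strata and returns the one-sided tail P(X >= sum O | Poisson(sum E)).
#'
#' @param o_per_stratum Observed counts per stratum.
#' @param e_per_stratum Expected counts per stratum, same order.
#' @return One-sided P value.
#' @export
gene_test_poisson <- function(o_per_stratum, e_per_stratum) {
  stopifnot(length(o_per_stratum) == length(e_per_stratum))
  poisson_tail_one_sided(sum(o_per_stratum), sum(e_per_stratum))
}

#' Exact sum-of-independent-binomials tail
#'
#' The exact reference for [gene_test_poisson()]: with N_p probands in
#' stratum p each carrying a biallelic genotype with probability lambda_p,
#' the total observed count is a sum of independent binomials. Returns
#' P(sum_p Binomial(N_p, lambda_p) >= o_total) by dynamic-programming
#' convolution of the per-stratum binomial PMFs truncated at `o_total`.
#' Intended for small totals; refuses (with an error pointing to the Poisson
#' approximation) when the predicted work exceeds `max_cells`.
#'
#' @param n_per_stratum Probands per stratum.
#' @param lambda_per_stratum Per-proband biallelic rate per stratum, in
#'   \[0, 1\].
#' @param o_total Total observed count.
#' @param max_cells Work budget: number of PMF cells (default 1e7).
#' @return Exact tail probability.
#' @export
gene_test_exact <- function(n_per_stratum, lambda_per_stratum, o_total,
                            max_cells = 1e7) {
  stopifnot(length(n_per_stratum) == length(lambda_per_stratum),
            all(lambda_per_stratum >= 0 & lambda_per_stratum <= 1),
            o_total >= 0)
  if (o_total == 0) return(1)
  k <- o_total  # need P(S <= o_total - 1); support 0..k-1
  work <- length(n_per_stratum) * k * k
  if (work > max_cells)
    stop("exact sum-of-binomials tail exceeds the work budget (",
         format(work, big.mark = ","), " cells); use gene_test_poisson()")
  # pmf of the running sum truncated to 0..k-1; mass crossing the truncation
  # bound is accumulated directly into the tail (numerically exact for small
  # tails, no 1 - sum cancellation)
  pmf <- c(1, numeric(k - 1))
  tail_mass <- 0
  for (i in seq_along(n_per_stratum)) {
    b <- stats::dbinom(0:(k - 1), n_per_stratum[i], lambda_per_stratum[i])
    new <- numeric(k)
    for (s in 0:(k - 1)) {
      if (pmf[s + 1] == 0) next
      top <- k - 1 - s
      new[s + 1:(top + 1)] <- new[s + 1:(top + 1)] + pmf[s + 1] * b[1:(top + 1)]
      tail_mass <- tail_mass + pmf[s + 1] *
        stats::pbinom(top, n_per_stratum[i], lambda_per_stratum[i],
                      lower.tail = FALSE)
    }
    pmf <- new
  }
  min(1, tail_mass)
}

#' Build the four damaging class-pair combinations per gene
#'
#' The four non-independent per-gene tests: LoF/LoF alone; LoF/LoF +
#' LoF/functional; functional/functional alone; and all three damaging
#' pairs combined. Observed and expected counts are summed over the
#' constituent class pairs and over strata.
#'
#' @param observed Observed count table (gene, class_pair, stratum, O).
#' @param expected Expectation table (gene, class_pair, stratum, E).
#' @param genes Optional gene universe; defaults to genes in `expected`.
#' @return A `data.table` (gene, combo, O_total, E_total).
#' @export
build_combos <- function(observed, expected, genes = NULL) {
  observed <- data.table::as.data.table(observed)
  expected <- data.table::as.data.table(expected)
  if (is.null(genes)) genes <- sort(unique(expected$gene))
  o_gene <- observed[class_pair %in% DAMAGING_PAIRS,
                     .(O = sum(O)), by = .(gene, class_pair)]
  e_gene <- expected[class_pair %in% DAMAGING_PAIRS,
                     .(E = sum(E)), by = .(gene, class_pair)]
  grid <- data.table::CJ(gene = genes, class_pair = DAMAGING_PAIRS)
  grid <- merge(grid, o_gene, by = c("gene", "class_pair"), all.x = TRUE)
  grid <- merge(grid, e_gene, by = c("gene", "class_pair"), all.x = TRUE)
  grid[is.na(O), O := 0L]
  grid[is.na(E), E := 0]
  out <- data.table::rbindlist(lapply(GENE_COMBOS, function(cb) {
    parts <- combo_parts(cb)
    grid[class_pair %in% parts,
         .(combo = cb, O_total = sum(O), E_total = sum(E)), by = gene]
  }))
  data.table::setkey(out, gene, combo)
  out[]
}

#' Multiple-testing correction for the per-gene tests
#'
#' Applies a Bonferroni threshold of alpha / (4 * G_universe) (four
#' class-pair combinations per gene over the configured gene universe) and
#' Benjamini-Hochberg FDR adjustment. By default BH is computed over the
#' concatenated vector of all four tests for every tested gene
#' (`method = "all_tests"`); `method = "min_p"` instead adjusts the per-gene
#' minimum P values over the tested genes.
#'
#' @param results A `data.table` with `gene`, `combo`, `p_value` (as from
#'   [gene_burden_test()]).
#' @param n_genes_universe Size of the full gene universe used in the
#'   Bonferroni denominator (may exceed the number of genes with passing
#'   variants, which is what BH sees).
#' @param alpha Family-wise error target for Bonferroni (default 0.05).
#' @param method BH mode, `"all_tests"` or `"min_p"`.
#' @return The input with added `q_value`, `bonferroni_significant` and
#'   `min_p_per_gene` (marks the row(s) attaining each gene's minimum P;
#'   ties broken by combo list order); the Bonferroni threshold is attached
#'   as attribute `bonferroni_threshold`.
#' @export
multiple_testing <- function(results, n_genes_universe, alpha = 0.05,
                             method = c("all_tests", "min_p")) {
  method <- match.arg(method)
  results <- data.table::copy(data.table::as.data.table(results))
  threshold <- alpha / (4 * n_genes_universe)
  results[, bonferroni_significant := p_value < threshold]
  if (method == "all_tests") {
    results[, q_value := stats::p.adjust(p_value, method = "BH")]
  } else {
    minp <- results[, .(p_value = min(p_value)), by = gene]
    minp[, q_value := stats::p.adjust(p_value, method = "BH")]
    results[, q_value := minp$q_value[match(gene, minp$gene)]]
  }
  results[, combo_order := match(combo, GENE_COMBOS)]
  results[, min_p_per_gene := seq_len(.N) == order(p_value, combo_order)[1],
          by = gene]
  results[, combo_order := NULL]
  data.table::setattr(results, "bonferroni_threshold", threshold)
  results[]
}

#' Per-gene burden test over all combinations
#'
#' Runs the sum-of-Poissons test for the four damaging class-pair
#' combinations of every gene and applies multiple-testing correction.
#'
#' @param observed Observed count table.
#' @param expected Expectation table.
#' @param genes Optional gene universe restriction for testing.
#' @param n_genes_universe Bonferroni denominator; defaults to the number of
#'   tested genes.
#' @param alpha Bonferroni family-wise alpha.
#' @param bh_method Passed to [multiple_testing()].
#' @return A `data.table` (gene, combo, O_total, E_total, p_value, q_value,
#'   bonferroni_significant, min_p_per_gene).
#' @export
gene_burden_test <- function(observed, expected, genes = NULL,
                             n_genes_universe = NULL, alpha = 0.05,
                             bh_method = "all_tests") {
  combos <- build_combos(observed, expected, genes = genes)
  combos[, p_value := poisson_tail_one_sided(O_total, E_total)]
  if (is.null(n_genes_universe))
    n_genes_universe <- length(unique(combos$gene))
  multiple_testing(combos, n_genes_universe, alpha = alpha,
                   method = bh_method)
}

#' Synonymous-class null check
#'
#' Per-gene two-sided Poisson tests on the synonymous/synonymous control
#' class (summing across strata), which should behave as a null: returns the
#' per-gene P values plus a uniformity summary (a Kolmogorov-Smirnov
#' statistic against Uniform(0,1), the count of genes below the Bonferroni
#' threshold for the tested genes, and the fraction of genes with p < 0.05).
#' The KS statistic is a qualitative diagnostic; synonymous counts are small
#' integers, so their P values are strongly discrete.
#'
#' @param observed Observed count table.
#' @param expected Expectation table.
#' @param alpha Bonferroni family-wise alpha for the summary count.
#' @return List: `per_gene` (gene, O_total, E_total, p_value), `ks_stat`,
#'   `n_below_bonferroni`, `prop_below_0.05`.
#' @export
synonymous_null_check <- function(observed, expected, alpha = 0.05) {
  observed <- data.table::as.data.table(observed)
  expected <- data.table::as.data.table(expected)
  e_gene <- expected[class_pair == "synonymous_synonymous",
                     .(E_total = sum(E)), by = gene]
  o_gene <- observed[class_pair == "synonymous_synonymous",
                     .(O_total = sum(O)), by = gene]
  per_gene <- merge(e_gene, o_gene, by = "gene", all.x = TRUE)
  per_gene[is.na(O_total), O_total := 0L]
  per_gene[, p_value := poisson_tail_two_sided(O_total, E_total)]
  ks <- suppressWarnings(stats::ks.test(per_gene$p_value, "punif"))
  list(
    per_gene = per_gene[],
    ks_stat = unname(ks$statistic),
    n_below_bonferroni = sum(per_gene$p_value < alpha / nrow(per_gene)),
    prop_below_0.05 = mean(per_gene$p_value < 0.05)
  )
}
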