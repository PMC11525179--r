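# Exome-wide and gene-set burden statistics: Poisson enrichment tests,
# attributable fraction with exact Poisson confidence intervals, pooled
# estimates, autozygosity calibration against the synonymous null, subgroup
# comparisons, residual risk, and diagnostic-yield arithmetic.

#' One- and two-sided Poisson tail tests
#'
#' `poisson_tail_one_sided(o, e)` returns P(X >= o) for X ~ Poisson(e): the
#' probability of observing at least `o` events given expectation `e`.
#' `poisson_tail_two_sided()` doubles the smaller tail,
#' min(1, 2 * min(P(X <= o), P(X >= o))), appropriate for the synonymous
#' control class where both deficits and excesses are of interest.
#'
#' `e = 0` with `o > 0` yields p = 0 with a warning (an impossible
#' observation under the model) rather than an error, so exome-wide sums are
#' never blocked by a degenerate gene.
#'
#' @param o Observed count(s), non-negative integer.
#' @param e Expected count(s) (Poisson rate), non-negative.
#' @return P value(s) in (0, 1\] (0 only in the degenerate e = 0 case).
#' @export
poisson_tail_one_sided <- function(o, e) {
  stopifnot(all(o >= 0), all(e >= 0))
  if (any(e == 0 & o > 0))
    warning("observed > 0 with expected = 0: returning p = 0")
  stats::ppois(o - 1, e, lower.tail = FALSE)
}

#' @rdname poisson_tail_one_sided
#' @export
poisson_tail_two_sided <- function(o, e) {
  stopifnot(all(o >= 0), all(e >= 0))
  if (any(e == 0 & o > 0))
    warning("observed > 0 with expected = 0: returning p = 0")
  lower <- stats::ppois(o, e)
  upper <- stats::ppois(o - 1, e, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Attributable fraction of probands with an excess biallelic genotype burden
#'
#' AF = (sum O - sum E) / N over the damaging class pairs (LoF/LoF,
#' LoF/functional, functional/functional): the estimated share of probands
#' explained by recessive coding causes in the chosen scope. The 95% CI
#' applies the exact (Garwood) Poisson interval to the summed observed count
#' and transforms it: ((O_lo - E)/N, (O_hi - E)/N). Pooling across strata or
#' cohorts sums numerators and denominators. The P value is the one-sided
#' Poisson tail of O given E.
#'
#' @param observed Observed count table (gene, class_pair, stratum, O), as
#'   from [tabulate_observed()] (sparse is fine).
#' @param expected Expectation table, as from [expectation_table()].
#' @param n_probands Named vector: probands per stratum (the scope's N).
#' @param gene_set Optional character vector restricting to a gene set.
#' @param exclude_genes Optional character vector of genes to drop.
#' @param class_pairs Class pairs to sum; default the three damaging pairs.
#' @param strata Optional subset of strata; default all in `n_probands`.
#' @param conf_level Confidence level for the AF interval (default 0.95).
#' @return An object of class `burden_result`: list with `O`, `E`, `N`, `af`,
#'   `af_ci`, `p_value`, `class_pairs`, `strata`.
#' @export
attributable_fraction <- function(observed, expected, n_probands,
                                  gene_set = NULL, exclude_genes = NULL,
                                  class_pairs = DAMAGING_PAIRS,
                                  strata = NULL, conf_level = 0.95) {
  observed <- data.table::as.data.table(observed)
  expected <- data.table::as.data.table(expected)
  if (is.null(strata)) strata <- names(n_probands)
  N <- sum(n_probands[strata])
  if (is.na(N) || N <= 0) stop("scope has no probands")
  sel <- function(dt) {
    dt <- dt[class_pair %in% class_pairs & stratum %in% strata]
    if (!is.null(gene_set)) dt <- dt[gene %in% gene_set]
    if (!is.null(exclude_genes)) dt <- dt[!gene %in% exclude_genes]
    dt
  }
  O <- sum(sel(observed)$O)
  E <- sum(sel(expected)$E)
  alpha <- 1 - conf_level
  o_lo <- if (O == 0) 0 else stats::qgamma(alpha / 2, O)
  o_hi <- stats::qgamma(1 - alpha / 2, O + 1)
  structure(
    list(
      O = O, E = E, N = N,
      af = (O - E) / N,
      af_ci = c((o_lo - E) / N, (o_hi - E) / N),
      p_value = poisson_tail_one_sided(O, E),
      conf_level = conf_level,
      class_pairs = class_pairs, strata = strata
    ),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    "<burden_result> O = %d, E = %.3f, N = %d\n  AF = %.4f (%d%% CI %.4f to %.4f), one-sided Poisson P = %.3g\n",
    x$O, x$E, x$N, x$af, round(100 * x$conf_level), x$af_ci[1], x$af_ci[2],
    x$p_value
  ))
  invisible(x)
}

#' Bootstrap confidence interval for the attributable fraction
#'
#' Alternative to the exact-Poisson interval of [attributable_fraction()]:
#' resamples probands with replacement within each stratum, recomputes
#' `(O* - E*) / N` per resample (per-proband expected rates are held fixed,
#' so `E*` scales with the resampled stratum sizes, which here equal the
#' originals), and returns percentile bounds.
#'
#' @param calls Deduplicated biallelic calls ([most_severe_dedup()]).
#' @param expected Expectation table.
#' @param meta Proband metadata (`trio_id`, `stratum`).
#' @param n_boot Number of bootstrap resamples.
#' @param gene_set,exclude_genes,class_pairs,strata,conf_level As in
#'   [attributable_fraction()].
#' @return A `burden_result` whose `af_ci` is the bootstrap percentile
#'   interval (with `n_boot` recorded).
#' @export
attributable_fraction_bootstrap <- function(calls, expected, meta,
                                            n_boot = 1000,
                                            gene_set = NULL,
                                            exclude_genes = NULL,
                                            class_pairs = DAMAGING_PAIRS,
                                            strata = NULL,
                                            conf_level = 0.95) {
  calls <- data.table::as.data.table(calls)
  expected <- data.table::as.data.table(expected)
  meta <- data.table::as.data.table(meta)
  if (is.null(strata)) strata <- sort(unique(meta$stratum))
  meta <- meta[stratum %in% strata]
  sel_calls <- calls[class_pair %in% class_pairs]
  if (!is.null(gene_set)) sel_calls <- sel_calls[gene %in% gene_set]
  if (!is.null(exclude_genes)) sel_calls <- sel_calls[!gene %in% exclude_genes]
  sel_exp <- expected[class_pair %in% class_pairs & stratum %in% strata]
  if (!is.null(gene_set)) sel_exp <- sel_exp[gene %in% gene_set]
  if (!is.null(exclude_genes)) sel_exp <- sel_exp[!gene %in% exclude_genes]

  # per-trio damaging call count within scope (a trio can contribute in
  # several genes)
  per_trio <- sel_calls[, .(count = .N), by = trio_id]
  meta <- merge(meta, per_trio, by = "trio_id", all.x = TRUE)
  meta[is.na(count), count := 0L]
  N <- nrow(meta)
  if (N == 0) stop("scope has no probands")
  E <- sum(sel_exp$E)
  O <- sum(meta$count)
  by_stratum <- split(meta$count, meta$stratum)
  boots <- vapply(seq_len(n_boot), function(b) {
    o_star <- sum(vapply(by_stratum, function(x)
      sum(sample(x, length(x), replace = TRUE)), 0))
    (o_star - E) / N
  }, 0)
  alpha <- 1 - conf_level
  structure(
    list(O = O, E = E, N = N, af = (O - E) / N,
         af_ci = unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2))),
         p_value = poisson_tail_one_sided(O, E),
         conf_level = conf_level, n_boot = n_boot,
         class_pairs = class_pairs, strata = strata),
    class = "burden_result"
  )
}

#' Choose the autozygosity calibration that best fits the synonymous null
#'
#' Runs of homozygosity can be called under several LD-thinning parameters,
#' each yielding a candidate autozygosity table and hence a candidate
#' expectation. Per stratum, the candidate whose exome-wide
#' synonymous/synonymous two-sided Poisson P value is largest (observed
#' closest to expected under the null-behaving control class) is selected,
#' and is then used for all variant classes. Ties are broken in favour of
#' the first-listed candidate.
#'
#' @param candidates Named list of expectation tables (one per ROH-calling
#'   parameter), each as from [expectation_table()].
#' @param observed Observed count table.
#' @param n_probands Named vector of probands per stratum.
#' @return A list with `choice` (data.table: stratum, candidate, syn_p) and
#'   `expected` (the per-stratum stitched expectation table).
#' @export
calibrate_autozygosity <- function(candidates, observed, n_probands) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  observed <- data.table::as.data.table(observed)
  strata <- names(n_probands)
  rows <- list()
  for (p in strata) {
    best <- NULL
    for (nm in names(candidates)) {
      exp_p <- data.table::as.data.table(candidates[[nm]])
      O <- sum(observed[class_pair == "synonymous_synonymous" & stratum == p]$O)
      E <- sum(exp_p[class_pair == "synonymous_synonymous" & stratum == p]$E)
      pv <- poisson_tail_two_sided(O, E)
      if (is.null(best) || pv > best$syn_p)  # strict >: first candidate wins ties
        best <- list(candidate = nm, syn_p = pv)
    }
    rows[[p]] <- data.table::data.table(stratum = p, candidate = best$candidate,
                                        syn_p = best$syn_p)
  }
  choice <- data.table::rbindlist(rows)
  expected <- data.table::rbindlist(lapply(strata, function(p) {
    nm <- choice[stratum == p]$candidate
    data.table::as.data.table(candidates[[nm]])[stratum == p]
  }))
  list(choice = choice[], expected = expected[])
}

#' Compare two attributable fractions
#'
#' Two-sided z-test for a difference in proportions between two independent
#' scopes, treating AF * N excess cases out of N probands in each
#' (unpooled variance).
#'
#' @param af1,af2 [attributable_fraction()] results (or lists with `af`, `N`).
#' @return List with `z`, `p_value`, `diff`.
#' @export
compare_af <- function(af1, af2) {
  p1 <- af1$af; n1 <- af1$N
  p2 <- af2$af; n2 <- af2$N
  if (n1 <= 0 || n2 <= 0) stop("non-positive proband count")
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), diff = p1 - p2)
}

#' Correlate attributable fraction with average autozygosity across strata
#'
#' Pearson correlation (with the standard t-based P value) between
#' per-stratum AF estimates and per-stratum mean F_ROH.
#'
#' @param af Numeric vector of per-stratum attributable fractions.
#' @param mean_froh Numeric vector of per-stratum mean F_ROH, same order.
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_af_autozygosity <- function(af, mean_froh) {
  stopifnot(length(af) == length(mean_froh))
  if (length(af) < 3) stop("need at least 3 strata")
  if (stats::sd(af) == 0 || stats::sd(mean_froh) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(af, mean_froh, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(af))
}

#' Residual recessive risk outside known disease genes
#'
#' For undiagnosed probands without a damaging biallelic genotype in a known
#' gene, estimates the attributable fraction restricted to genes off the
#' known list, separately in low (F_ROH < threshold) and high
#' (F_ROH > threshold) autozygosity groups. The default threshold 0.0156 is
#' the expected inbreeding coefficient for offspring of second cousins
#' ([cousin_offspring_froh()]).
#'
#' The caller supplies observed/expected tables already restricted to the
#' residual-risk proband set (diagnosed probands and probands with a passing
#' damaging biallelic genotype in a known gene removed), split by F_ROH
#' group; this function applies the gene-list exclusion and the AF machinery.
#'
#' @param observed_by_group,expected_by_group Named lists (`low`, `high`) of
#'   observed / expected tables for the two F_ROH groups.
#' @param n_probands_by_group Named list (`low`, `high`) of per-stratum
#'   proband counts.
#' @param known_genes Character vector of known disease genes to exclude.
#' @param froh_threshold The F_ROH split point (default 0.0156).
#' @return Named list (`low`, `high`) of `burden_result`s (an empty group is
#'   reported as `NULL`).
#' @export
residual_risk <- function(observed_by_group, expected_by_group,
                          n_probands_by_group, known_genes,
                          froh_threshold = 0.0156) {
  out <- list(froh_threshold = froh_threshold)
  for (grp in c("low", "high")) {
    n <- n_probands_by_group[[grp]]
    if (is.null(n) || sum(n) == 0) {
      out[[grp]] <- NULL
      next
    }
    out[[grp]] <- attributable_fraction(
      observed_by_group[[grp]], expected_by_group[[grp]], n,
      exclude_genes = known_genes
    )
  }
  out
}

#' Expected inbreeding coefficient for offspring of k-th cousins
#'
#' By pedigree path counting, offspring of k-th cousins have expected
#' inbreeding coefficient 4^-(k+1): 1/16 for first cousins, 1/64 = 0.015625
#' for second cousins (the conventional consanguinity threshold on F_ROH).
#'
#' @param k Cousin degree, integer >= 1.
#' @return Expected inbreeding coefficient.
#' @export
cousin_offspring_froh <- function(k) {
  if (any(k < 1) || any(k != round(k))) stop("k must be an integer >= 1")
  4^-(k + 1)
}

#' Diagnostic-yield arithmetic from an attributable fraction
#'
#' Converts an attributable-fraction estimate among undiagnosed probands
#' into: the number of additional diagnoses expected
#' (`round(af * n_undiagnosed)`), the fraction of all diagnoses currently
#' missed (`additional / (confirmed + additional)`), and, when the number of
#' reported candidate genotypes is given, the fraction of those candidates
#' expected to be truly pathogenic (`af * n_undiagnosed /
#' reported_candidates`).
#'
#' @param confirmed Number of confirmed diagnoses.
#' @param af Attributable fraction among undiagnosed probands.
#' @param n_undiagnosed Number of undiagnosed probands.
#' @param reported_candidates Optional count of reported candidate genotypes.
#' @return List with `additional`, `missing_fraction` and (if requested)
#'   `pathogenic_fraction`.
#' @export
diagnostic_yield <- function(confirmed, af, n_undiagnosed,
                             reported_candidates = NULL) {
  stopifnot(confirmed >= 0, n_undiagnosed >= 0)
  additional <- round(af * n_undiagnosed)
  out <- list(
    additional = additional,
    missing_fraction = if (confirmed + additional == 0) 0
                       else additional / (confirmed + additional)
  )
  if (!is.null(reported_candidates)) {
    if (reported_candidates == 0)
      stop("reported_candidates must be positive to compute pathogenic_fraction")
    out$pathogenic_fraction <- (af * n_undiagnosed) / reported_candidates
  }
  out
}
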