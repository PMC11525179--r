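# End-to-end convenience: from a cohort's inputs (variant annotations, trio
# genotypes, ROH, gene intervals, metadata) to observed and expected
# biallelic genotype counts, ready for burden and gene tests.

#' Run the burden pipeline on a cohort
#'
#' Classifies variants, Mendelian-filters the trio genotypes, detects and
#' deduplicates observed biallelic genotypes, estimates cumulative parental
#' haplotype frequencies (from the trio parents with transmission phasing,
#' or from an independent frequency panel), computes per-gene autozygosity
#' from ROH, and assembles the expectation table.
#'
#' @param cohort An `rb_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]), or any list with elements `variants`, `trios`, `meta`,
#'   `roh`, `genes`, `genome_length` and (for panel mode) `panel`,
#'   `panel_meta`.
#' @param freq_mode `"parents"` (cumulative frequencies from the trio
#'   parents, transmission-phased) or `"panel"` (from the independent
#'   frequency panel).
#' @param config A [filter_config()] for classification.
#' @param clinvar_mode Passed to [apply_clinvar_mask()].
#' @return A list: `observed` (sparse O table), `expected` (full E table),
#'   `n_probands` (named per-stratum vector), `calls`, `freqs`,
#'   `autozygosity`, `froh` (per-proband), `meta`, `variants` (classified).
#' @export
run_burden_pipeline <- function(cohort,
                                freq_mode = c("parents", "panel"),
                                config = filter_config(),
                                clinvar_mode = "keep_all") {
  freq_mode <- match.arg(freq_mode)
  variants <- classify_variants(cohort$variants, config)
  variants <- apply_clinvar_mask(variants, clinvar_mode)
  meta <- data.table::as.data.table(cohort$meta)
  trios <- mendelian_filter(cohort$trios)
  calls <- most_severe_dedup(detect_biallelic(trios, variants))
  observed <- tabulate_observed(calls, meta)
  freqs <- if (freq_mode == "parents") {
    haplotype_frequencies(trios, variants, meta)
  } else {
    panel_frequencies(cohort$panel, variants, cohort$panel_meta)
  }
  genes_gr <- genes_as_granges(data.table::as.data.table(cohort$genes))
  roh_gr <- roh_as_granges(data.table::as.data.table(cohort$roh))
  autozygosity <- gene_autozygosity(roh_gr, genes_gr, meta)
  n_probands <- table(meta$stratum)
  n_probands <- stats::setNames(as.integer(n_probands), names(n_probands))
  expected <- expectation_table(freqs, autozygosity, n_probands,
                                genes = sort(unique(cohort$genes$gene)))
  froh <- froh_per_proband(roh_gr, meta, cohort$genome_length)
  list(observed = observed, expected = expected, n_probands = n_probands,
       calls = calls, freqs = freqs, autozygosity = autozygosity,
       froh = froh, meta = meta, variants = variants)
}

#' Residual recessive risk from a pipeline result
#'
#' Implements the residual-risk procedure on a cohort: removes diagnosed
#' probands and probands with a damaging biallelic genotype in a known gene,
#' splits the remaining probands into low (F_ROH < threshold) and high
#' (F_ROH > threshold) autozygosity groups, and computes the attributable
#' fraction restricted to genes off the known list within each group
#' (per-proband expected rates held fixed, expectations scaled to each
#' group's size).
#'
#' @param pipeline A [run_burden_pipeline()] result.
#' @param known_genes Character vector of known disease genes.
#' @param froh_threshold F_ROH split point; default 0.0156, the expectation
#'   for offspring of second cousins.
#' @return As [residual_risk()]: list with `low`/`high` `burden_result`s
#'   (NULL for an empty group) and the threshold.
#' @export
residual_risk_cohort <- function(pipeline, known_genes,
                                 froh_threshold = 0.0156) {
  meta <- merge(pipeline$meta, pipeline$froh, by = "trio_id")
  has_known <- unique(pipeline$calls[
    class_pair %in% DAMAGING_PAIRS & gene %in% known_genes]$trio_id)
  keep <- meta[diagnosed == FALSE & !trio_id %in% has_known]
  groups <- list(low = keep[froh < froh_threshold],
                 high = keep[froh > froh_threshold])
  obs_by <- list(); exp_by <- list(); n_by <- list()
  for (grp in names(groups)) {
    g <- groups[[grp]]
    if (nrow(g) == 0) next
    n_grp <- table(g$stratum)
    n_by[[grp]] <- stats::setNames(as.integer(n_grp), names(n_grp))
    calls_g <- pipeline$calls[trio_id %in% g$trio_id]
    obs_by[[grp]] <- tabulate_observed(calls_g, g)
    e <- data.table::copy(pipeline$expected)[stratum %in% names(n_grp)]
    # rescale stratum expectations to the group's proband counts
    e[, E := lambda * n_by[[grp]][stratum]]
    exp_by[[grp]] <- e
  }
  residual_risk(obs_by, exp_by, n_by, known_genes,
                froh_threshold = froh_threshold)
}

#' Summarize a pipeline result as an exchangeable cohort summary
#'
#' Collapses a [run_burden_pipeline()] result to the federated exchange
#' format: per-cell observed/expected counts plus per-stratum sample sizes
#' and mean autozygosity.
#'
#' @param pipeline A [run_burden_pipeline()] result.
#' @return A [cohort_summary()].
#' @export
as_cohort_summary <- function(pipeline) {
  counts <- merge(
    pipeline$expected[, .(gene, class_pair, stratum, E)],
    pipeline$observed, by = c("gene", "class_pair", "stratum"), all.x = TRUE
  )
  counts[is.na(O), O := 0L]
  n_haps <- attr(pipeline$freqs, "n_haps_per_stratum")
  froh_by <- merge(pipeline$meta[, .(trio_id, stratum)], pipeline$froh,
                   by = "trio_id")
  strata <- froh_by[, .(mean_froh = mean(froh)), by = stratum]
  strata[, n_probands := pipeline$n_probands[stratum]]
  strata[, n_parent_haplotypes := n_haps[stratum]]
  cohort_summary(counts, strata)
}
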