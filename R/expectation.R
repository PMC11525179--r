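# Expected biallelic genotype counts: cumulative parental haplotype
# frequencies with transmission-based phasing, per-gene autozygosity, and the
# rate formulas combining the two.

#' Cumulative haplotype frequency
#'
#' f = h / n_haps: the fraction of parental haplotypes in a stratum carrying
#' at least one rare variant of a class in a gene.
#'
#' @param h Haplotype count(s).
#' @param n_haps Total number of parental haplotypes (2 per parent); must be
#'   positive.
#' @return Numeric in \[0, 1\].
#' @export
cumulative_frequency <- function(h, n_haps) {
  if (any(n_haps <= 0))
    stop("n_haps must be positive; exclude strata without eligible parents")
  if (any(h < 0 | h > n_haps)) stop("h must lie in [0, n_haps]")
  h / n_haps
}

#' Estimate cumulative haplotype frequencies from trio parents
#'
#' For each (gene, class, stratum), counts parental haplotypes carrying at
#' least one variant of the class among eligible (unrelated, unaffected)
#' parents, using the rules of [count_parental_haplotypes()]: 2 for a
#' homozygous-alternate genotype, 1 for a single heterozygote, and for
#' multiple heterozygotes 2 when transmission to the child demonstrates
#' trans phase, else 1.
#'
#' Genotypes should already be Mendelian-filtered ([mendelian_filter()]).
#'
#' @param trios Long-format trio genotypes.
#' @param variants Classified variant table.
#' @param meta Proband metadata with `stratum`, `mother_eligible`,
#'   `father_eligible`.
#' @return A `data.table` (gene, class, stratum, h, n_haps, f); sparse in
#'   gene/class (absent cells have h = 0), with the per-stratum `n_haps`
#'   recoverable from any row of that stratum or via
#'   `attr(x, "n_haps_per_stratum")`.
#' @export
haplotype_frequencies <- function(trios, variants, meta) {
  trios <- data.table::as.data.table(trios)
  variants <- data.table::as.data.table(variants)
  meta <- data.table::as.data.table(meta)
  if (!"mother_eligible" %in% names(meta)) meta[, mother_eligible := TRUE]
  if (!"father_eligible" %in% names(meta)) meta[, father_eligible := TRUE]
  n_parents <- meta[, .(n_parents = sum(mother_eligible) + sum(father_eligible)),
                    by = stratum]
  n_haps_map <- stats::setNames(2L * n_parents$n_parents, n_parents$stratum)

  vcols <- intersect(c("variant_id", "gene", "class", "chrom"), names(variants))
  m <- merge(trios, variants[, vcols, with = FALSE], by = "variant_id")
  if ("chrom" %in% names(m)) m <- m[!chrom %in% c("X", "chrX", "Y", "chrY")]
  m <- m[class %in% c("LoF", "functional", "synonymous_control")]
  m <- merge(m, meta[, .(trio_id, stratum, mother_eligible, father_eligible)],
             by = "trio_id")

  count_side <- function(dt, parent_col, other_col, eligible_col) {
    d <- dt[dt[[eligible_col]] & dt[[parent_col]] >= 1L]
    if (nrow(d) == 0)
      return(data.table::data.table(gene = character(), class = character(),
                                    stratum = character(), h = integer()))
    d[, parent_gt := d[[parent_col]]]
    d[, status := transmission_status(parent_gt, gt_proband, d[[other_col]])]
    per_parent <- d[, .(
      n_hom = sum(parent_gt == 2L),
      n_het = sum(parent_gt == 1L),
      n_trans = sum(parent_gt == 1L & status == 1L),
      n_untrans = sum(parent_gt == 1L & status == -1L)
    ), by = .(trio_id, gene, class, stratum)]
    per_parent[, h := data.table::fifelse(
      n_hom > 0L, 2L,
      data.table::fifelse(n_het == 0L, 0L,
        data.table::fifelse(n_het == 1L, 1L,
          data.table::fifelse(n_trans > 0L & n_untrans > 0L, 2L, 1L))))]
    per_parent[, .(h = sum(h)), by = .(gene, class, stratum)]
  }
  h_all <- data.table::rbindlist(list(
    count_side(m, "gt_mother", "gt_father", "mother_eligible"),
    count_side(m, "gt_father", "gt_mother", "father_eligible")
  ))
  out <- h_all[, .(h = sum(h)), by = .(gene, class, stratum)]
  out[, n_haps := n_haps_map[stratum]]
  out[, f := cumulative_frequency(h, n_haps)]
  data.table::setkey(out, gene, class, stratum)
  data.table::setattr(out, "n_haps_per_stratum", n_haps_map)
  out[]
}

#' Estimate cumulative haplotype frequencies from an independent parent panel
#'
#' As [haplotype_frequencies()], but for a frequency panel of parents without
#' offspring genotypes: a homozygous-alternate genotype counts 2 haplotypes,
#' otherwise any heterozygous genotype counts 1 (multi-heterozygote phase is
#' unresolvable without transmission).
#'
#' @param panel Long-format genotypes: `parent_id`, `variant_id`, `gt`.
#' @param variants Classified variant table.
#' @param panel_meta `data.table` with `parent_id`, `stratum` (one row per
#'   panel parent, carriers or not).
#' @return As [haplotype_frequencies()].
#' @export
panel_frequencies <- function(panel, variants, panel_meta) {
  panel <- data.table::as.data.table(panel)
  variants <- data.table::as.data.table(variants)
  panel_meta <- data.table::as.data.table(panel_meta)
  n_haps_map <- panel_meta[, .(n = 2L * .N), by = stratum]
  n_haps_map <- stats::setNames(n_haps_map$n, n_haps_map$stratum)
  vcols <- intersect(c("variant_id", "gene", "class", "chrom"), names(variants))
  m <- merge(panel, variants[, vcols, with = FALSE], by = "variant_id")
  if ("chrom" %in% names(m)) m <- m[!chrom %in% c("X", "chrX", "Y", "chrY")]
  m <- m[class %in% c("LoF", "functional", "synonymous_control") & gt >= 1L]
  m <- merge(m, panel_meta[, .(parent_id, stratum)], by = "parent_id")
  per_parent <- m[, .(h = data.table::fifelse(any(gt == 2L), 2L, 1L)),
                  by = .(parent_id, gene, class, stratum)]
  out <- per_parent[, .(h = sum(h)), by = .(gene, class, stratum)]
  out[, n_haps := n_haps_map[stratum]]
  out[, f := cumulative_frequency(h, n_haps)]
  data.table::setkey(out, gene, class, stratum)
  data.table::setattr(out, "n_haps_per_stratum", n_haps_map)
  out[]
}

#' Per-gene autozygosity and per-proband F_ROH
#'
#' `gene_autozygosity()` computes a_{p,g}: the proportion of probands in
#' stratum p whose runs of homozygosity (ROH) overlap gene g by at least
#' 1 bp. `froh_per_proband()` computes each proband's F_ROH: the fraction of
#' the autosomal genome covered by its (merged) ROH intervals.
#'
#' @param roh `GRanges` of ROH intervals with a `name` column holding the
#'   proband's `trio_id` (see [read_bed()]); probands with no ROH simply have
#'   no intervals.
#' @param genes `GRanges` of gene intervals with `name` = gene symbol.
#' @param meta Proband metadata (`trio_id`, `stratum`); defines the proband
#'   denominator per stratum (must be non-empty).
#' @return `gene_autozygosity()`: a `data.table` (stratum, gene, a), sparse
#'   (absent cells have a = 0). `froh_per_proband()`: a `data.table`
#'   (trio_id, froh) covering every proband in `meta`.
#' @export
gene_autozygosity <- function(roh, genes, meta) {
  meta <- data.table::as.data.table(meta)
  if (nrow(meta) == 0) stop("no probands in metadata")
  n_strat <- meta[, .(n = .N), by = stratum]
  hits <- GenomicRanges::findOverlaps(genes, roh)
  if (length(hits) == 0)
    return(data.table::data.table(stratum = character(), gene = character(),
                                  a = numeric()))
  dt <- data.table::data.table(
    gene = genes$name[S4Vectors::queryHits(hits)],
    trio_id = roh$name[S4Vectors::subjectHits(hits)]
  )
  dt <- unique(dt)
  dt <- merge(dt, meta[, .(trio_id, stratum)], by = "trio_id")
  out <- dt[, .(count = .N), by = .(stratum, gene)]
  out <- merge(out, n_strat, by = "stratum")
  out[, a := count / n]
  out[, c("count", "n") := NULL]
  data.table::setkey(out, stratum, gene)
  out[]
}

#' @rdname gene_autozygosity
#' @param genome_length Total autosomal genome length (bp) used as the F_ROH
#'   denominator; the default is the conventional human autosome total
#'   (~2.88 Gb). Synthetic cohorts carry their own toy genome length.
#' @export
froh_per_proband <- function(roh, meta, genome_length = 2.88e9) {
  meta <- data.table::as.data.table(meta)
  stopifnot(genome_length > 0)
  if (length(roh) == 0) {
    return(data.table::data.table(trio_id = meta$trio_id, froh = 0))
  }
  merged <- GenomicRanges::reduce(
    GenomicRanges::split(roh, roh$name)
  )
  widths <- sum(GenomicRanges::width(merged))
  dt <- data.table::data.table(trio_id = names(widths),
                               froh = as.numeric(widths) / genome_length)
  out <- merge(meta[, .(trio_id)], dt, by = "trio_id", all.x = TRUE)
  out[is.na(froh), froh := 0]
  if (any(out$froh > 1)) stop("F_ROH > 1: check genome_length")
  out[]
}

#' Biallelic genotype rate under autozygosity
#'
#' The per-proband rate of a within-class biallelic genotype:
#' lambda = (1 - a) * f^2 + a * f, a convex combination of the panmictic
#' rate f^2 and the autozygous rate f. Monotone non-decreasing in both
#' arguments; f^2 <= lambda <= f.
#'
#' @param f Cumulative haplotype frequency in \[0, 1\].
#' @param a Proportion of probands with an ROH overlapping the gene, in
#'   \[0, 1\].
#' @return Numeric rate(s) in \[0, 1\].
#' @export
lambda_biallelic <- function(f, a) {
  stopifnot(all(f >= 0 & f <= 1), all(a >= 0 & a <= 1))
  (1 - a) * f^2 + a * f
}

#' LoF/functional compound-heterozygote rate
#'
#' lambda = (1 - a) * 2 * f_lof * f_functional * (1 - f_lof): a cross-class
#' compound heterozygote requires a non-autozygous gene copy pair, one
#' haplotype carrying a LoF and the other carrying a functional variant but
#' no LoF (a haplotype with both would make the genotype LoF/LoF).
#'
#' @param f_lof,f_functional Cumulative haplotype frequencies in \[0, 1\].
#' @param a Autozygosity proportion in \[0, 1\].
#' @return Numeric rate(s).
#' @export
lambda_comphet_lof_functional <- function(f_lof, f_functional, a) {
  stopifnot(all(f_lof >= 0 & f_lof <= 1),
            all(f_functional >= 0 & f_functional <= 1),
            all(a >= 0 & a <= 1))
  (1 - a) * 2 * f_lof * f_functional * (1 - f_lof)
}

#' Expected biallelic genotype counts
#'
#' Builds the full expectation table E(b_{c,p,g}) = N_probands_p *
#' lambda_{c,p,g} over every (gene, class pair, stratum): within-class pairs
#' (LoF/LoF, functional/functional, synonymous/synonymous) use
#' [lambda_biallelic()] on that class's cumulative frequency, and
#' LoF/functional uses [lambda_comphet_lof_functional()].
#'
#' @param freqs Output of [haplotype_frequencies()] or [panel_frequencies()].
#' @param autozygosity Output of [gene_autozygosity()]; strata with no
#'   autozygosity rows at all default to a = 0 with a warning.
#' @param n_probands Named integer vector: probands per stratum.
#' @param genes Optional character vector fixing the gene universe; defaults
#'   to the genes present in `freqs`.
#' @return A `data.table` (gene, class_pair, stratum, a, lambda, E,
#'   n_probands), one row per cell of the full grid.
#' @export
expectation_table <- function(freqs, autozygosity, n_probands, genes = NULL) {
  freqs <- data.table::as.data.table(freqs)
  autozygosity <- data.table::as.data.table(autozygosity)
  strata <- names(n_probands)
  if (is.null(strata)) stop("n_probands must be a named vector")
  if (is.null(genes)) genes <- sort(unique(freqs$gene))
  no_a <- setdiff(strata, unique(autozygosity$stratum))
  if (length(no_a))
    warning("no autozygosity data for stratum/strata ",
            paste(no_a, collapse = ", "), "; assuming a = 0 there")

  grid <- data.table::CJ(gene = genes, stratum = strata)
  fw <- data.table::dcast(freqs[gene %in% genes], gene + stratum ~ class,
                          value.var = "f", fill = 0)
  for (cl in c("LoF", "functional", "synonymous_control"))
    if (!cl %in% names(fw)) fw[[cl]] <- 0
  grid <- merge(grid, fw, by = c("gene", "stratum"), all.x = TRUE)
  for (cl in c("LoF", "functional", "synonymous_control"))
    grid[is.na(get(cl)), (cl) := 0]
  grid <- merge(grid, autozygosity, by = c("gene", "stratum"), all.x = TRUE)
  if (!"a" %in% names(grid)) grid[, a := 0]
  grid[is.na(a), a := 0]

  long <- data.table::rbindlist(list(
    grid[, .(gene, stratum, class_pair = "lof_lof", a,
             lambda = lambda_biallelic(LoF, a))],
    grid[, .(gene, stratum, class_pair = "lof_functional", a,
             lambda = lambda_comphet_lof_functional(LoF, functional, a))],
    grid[, .(gene, stratum, class_pair = "functional_functional", a,
             lambda = lambda_biallelic(functional, a))],
    grid[, .(gene, stratum, class_pair = "synonymous_synonymous", a,
             lambda = lambda_biallelic(synonymous_control, a))]
  ))
  long[, n_probands := n_probands[stratum]]
  long[, E := n_probands * lambda]
  data.table::setkey(long, gene, class_pair, stratum)
  long[]
}
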