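# Consequence-class assignment and the rarity / region / ClinVar filters that
# define the analysis variant set.

# Controlled vocabulary, canonical-transcript consequences.
# LoF terms count as LoF only at high predicted confidence; low-confidence
# LoFs fall into the functional class.
LOF_CONSEQUENCES <- c(
  "splice_donor_variant", "splice_acceptor_variant", "stop_gained",
  "frameshift_variant", "stop_lost", "transcript_ablation"
)

FUNCTIONAL_CONSEQUENCES <- c(
  "missense_variant", "inframe_insertion", "inframe_deletion", "start_lost",
  "transcript_amplification", "protein_altering_variant",
  "splice_region_variant"
)

VARIANT_CLASSES <- c("LoF", "functional", "synonymous_control", "excluded")

#' Filtering configuration
#'
#' Bundles the thresholds that define the analysis variant set: rarity bounds
#' in the local parental strata and in the reference populations, the minimum
#' parental sample size for a stratum's frequency to be binding, and the
#' splice-disruption score cut-offs that route synonymous variants either into
#' the control class or into the functional class.
#'
#' The local bound is inclusive (frequency <= `local_maf_max`) while the
#' reference bound is exclusive (< `reference_maf_max`); the asymmetry is
#' intentional and mirrors how the two filters are usually stated.
#'
#' @param local_maf_max Maximum allele frequency among unrelated, unaffected
#'   parents of any binding stratum (inclusive). Default 0.005.
#' @param reference_maf_max Reference-population allele frequency bound
#'   (exclusive). Default 0.005.
#' @param min_parents_per_stratum Minimum number of unrelated, unaffected
#'   parents for a stratum's local frequency to be binding. Default 150.
#' @param splice_control_max Synonymous variants with splice-disruption score
#'   strictly below this are controls. Default 0.1.
#' @param splice_functional_min Synonymous variants with score at or above
#'   this are treated as functional (cryptic splice). Default 0.8.
#' @param functional_extra_filter Optional `list(score_column=, threshold=)`
#'   hook for an additional missense deleteriousness filter; variants of the
#'   functional class with score below the threshold are excluded. Default
#'   `NULL` (off). This hook is a placeholder for cohort-specific missense
#'   filters, not a recommended default.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(local_maf_max = 0.005,
                          reference_maf_max = 0.005,
                          min_parents_per_stratum = 150,
                          splice_control_max = 0.1,
                          splice_functional_min = 0.8,
                          functional_extra_filter = NULL) {
  stopifnot(
    local_maf_max >= 0, local_maf_max <= 1,
    reference_maf_max >= 0, reference_maf_max <= 1,
    splice_control_max >= 0,
    splice_control_max <= splice_functional_min,
    splice_functional_min <= 1
  )
  structure(
    list(
      local_maf_max = local_maf_max,
      reference_maf_max = reference_maf_max,
      min_parents_per_stratum = min_parents_per_stratum,
      splice_control_max = splice_control_max,
      splice_functional_min = splice_functional_min,
      functional_extra_filter = functional_extra_filter
    ),
    class = "filter_config"
  )
}

#' Assign a consequence class to variants
#'
#' Maps (consequence, LoF confidence, splice-disruption score) to one of
#' `LoF`, `functional`, `synonymous_control`, `excluded`:
#' * LoF-type consequences at high confidence -> `LoF`; at lower confidence
#'   they are demoted to `functional`.
#' * Protein-altering consequences (missense, in-frame indels, start lost,
#'   splice region, ...) -> `functional`.
#' * Synonymous variants with splice score < `splice_control_max` ->
#'   `synonymous_control`; with score >= `splice_functional_min` ->
#'   `functional` (predicted cryptic splice); in between -> `excluded`.
#' * Unknown consequence terms -> `excluded` with a warning.
#'
#' @param raw_consequence Character vector of consequence terms.
#' @param lof_confidence Character vector in `high`, `low`, `not_applicable`.
#' @param splice_score Numeric vector in \[0, 1\].
#' @param config A [filter_config()].
#' @return Character vector of classes, same length as the inputs.
#' @export
classify_variant <- function(raw_consequence, lof_confidence, splice_score,
                             config = filter_config()) {
  n <- length(raw_consequence)
  stopifnot(length(lof_confidence) == n, length(splice_score) == n)
  if (any(!is.na(splice_score) & (splice_score < 0 | splice_score > 1)))
    stop("splice_score must lie in [0, 1]")
  splice_score[is.na(splice_score)] <- 0
  cls <- rep("excluded", n)
  is_lof_term <- raw_consequence %in% LOF_CONSEQUENCES
  cls[is_lof_term & lof_confidence == "high"] <- "LoF"
  cls[is_lof_term & lof_confidence != "high"] <- "functional"
  cls[raw_consequence %in% FUNCTIONAL_CONSEQUENCES] <- "functional"
  is_syn <- raw_consequence == "synonymous_variant"
  cls[is_syn & splice_score < config$splice_control_max] <- "synonymous_control"
  cls[is_syn & splice_score >= config$splice_functional_min] <- "functional"
  known <- is_lof_term | is_syn | raw_consequence %in% FUNCTIONAL_CONSEQUENCES
  if (any(!known)) {
    warning(sprintf(
      "%d variant(s) with consequence term(s) outside the controlled vocabulary were excluded: %s",
      sum(!known), paste(unique(raw_consequence[!known]), collapse = ", ")
    ))
  }
  cls
}

#' Classify a variant table
#'
#' Adds/overwrites a `class` column on an annotated variant table (see
#' [read_variant_table()]) using [classify_variant()], and applies the
#' optional extra functional deleteriousness filter if configured.
#'
#' @param variants A variant `data.table`.
#' @param config A [filter_config()].
#' @return The variant table with a `class` column (a new data.table).
#' @export
classify_variants <- function(variants, config = filter_config()) {
  variants <- data.table::as.data.table(variants)
  variants[, class := classify_variant(consequence, lof_confidence,
                                       splice_score, config)]
  hook <- config$functional_extra_filter
  if (!is.null(hook)) {
    col <- hook$score_column
    if (!col %in% names(variants))
      stop(sprintf("functional_extra_filter column '%s' not present", col))
    demote <- variants$class == "functional" &
      variants$consequence == "missense_variant" &
      !is.na(variants[[col]]) & variants[[col]] < hook$threshold
    variants[demote, class := "excluded"]
  }
  variants[]
}

#' Rarity filter
#'
#' A variant passes iff its allele frequency is at most
#' `config$local_maf_max` in every *binding* local stratum (a stratum is
#' binding when it has at least `config$min_parents_per_stratum` unrelated,
#' unaffected parents), strictly below `config$reference_maf_max` in every
#' reference population, and it has zero homozygotes in the reference
#' database.
#'
#' @param variants Variant table with `stratum:<p>` frequency columns,
#'   `ref:<pop>` frequency columns and `ref_hom_count`.
#' @param parent_counts Named integer vector: number of unrelated, unaffected
#'   parents per stratum label (names match the `<p>` of the `stratum:` columns).
#' @param config A [filter_config()].
#' @return Logical vector, one element per variant.
#' @export
passes_rarity <- function(variants, parent_counts, config = filter_config()) {
  variants <- data.table::as.data.table(variants)
  local_cols <- grep("^stratum:", names(variants), value = TRUE)
  ref_cols <- grep("^ref:", names(variants), value = TRUE)
  ok <- rep(TRUE, nrow(variants))
  for (col in local_cols) {
    p <- sub("^stratum:", "", col)
    n_par <- parent_counts[[p]]
    if (is.null(n_par) || is.na(n_par))
      stop(sprintf("no parent count supplied for stratum '%s'", p))
    if (n_par < config$min_parents_per_stratum) next  # non-binding stratum
    freq <- variants[[col]]
    ok <- ok & (is.na(freq) | freq <= config$local_maf_max)
  }
  for (col in ref_cols) {
    freq <- variants[[col]]
    ok <- ok & (is.na(freq) | freq < config$reference_maf_max)
  }
  ok & variants$ref_hom_count == 0
}

#' Region filter
#'
#' A variant passes iff its position overlaps the intersection of the exome
#' capture bait regions and overlaps neither the segmental-duplication nor
#' the simple-repeat exclusion intervals.
#'
#' @param variants Variant table with `chrom` and `pos` (1-based) columns.
#' @param bait_intersection,segdups,repeats `GRanges` interval sets (see
#'   [read_bed()]); `segdups`/`repeats` may be `NULL` meaning no exclusions.
#' @return Logical vector, one element per variant.
#' @export
passes_region <- function(variants, bait_intersection,
                          segdups = NULL, repeats = NULL) {
  variants <- data.table::as.data.table(variants)
  vr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, width = 1L)
  )
  ok <- IRanges::overlapsAny(vr, bait_intersection)
  if (!is.null(segdups)) ok <- ok & !IRanges::overlapsAny(vr, segdups)
  if (!is.null(repeats)) ok <- ok & !IRanges::overlapsAny(vr, repeats)
  ok
}

#' ClinVar pathogenic/likely-pathogenic mask
#'
#' With `mode = "drop_plp"`, removes variants flagged as pathogenic or likely
#' pathogenic in ClinVar before any counting; `mode = "keep_all"` is the
#' identity. Running the burden analysis under both modes measures the share
#' of the recessive burden explained by already-reported pathogenic variants.
#'
#' @param variants Variant table with logical `clinvar_plp`.
#' @param mode `"keep_all"` or `"drop_plp"`.
#' @return The (possibly subset) variant table.
#' @export
apply_clinvar_mask <- function(variants, mode = c("keep_all", "drop_plp")) {
  mode <- match.arg(mode)
  variants <- data.table::as.data.table(variants)
  if (mode == "keep_all") return(variants)
  variants[clinvar_plp == FALSE | is.na(clinvar_plp)]
}
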