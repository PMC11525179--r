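# Observed biallelic genotypes in trios: Mendelian filtering, detection of
# homozygous-alternate and transmission-phased compound-heterozygous
# genotypes, most-severe deduplication, and tabulation of O_{c,p,g}.

CLASS_SEVERITY <- c(lof_lof = 1L, lof_functional = 2L,
                    functional_functional = 3L)

pair_name <- function(c1, c2) {
  key <- c(LoF = "lof", functional = "functional",
           synonymous_control = "synonymous")
  paste(key[[c1]], key[[c2]], sep = "_")
}

#' Mendelian filter for trio genotypes
#'
#' A trio genotype at one variant is kept iff no member is missing and the
#' proband genotype is possible under biallelic Mendelian transmission given
#' the parental genotypes (each parent transmits exactly one allele).
#'
#' @param gt_proband,gt_mother,gt_father Integer genotype vectors
#'   (alternate-allele counts 0/1/2; NA = missing).
#' @return Logical vector: `TRUE` = keep.
#' @export
mendelian_keep <- function(gt_proband, gt_mother, gt_father) {
  complete <- !is.na(gt_proband) & !is.na(gt_mother) & !is.na(gt_father)
  ok <- complete
  p0 <- complete & gt_proband == 0L
  p1 <- complete & gt_proband == 1L
  p2 <- complete & gt_proband == 2L
  ok[p0] <- gt_mother[p0] <= 1L & gt_father[p0] <= 1L
  ok[p1] <- !(gt_mother[p1] == 0L & gt_father[p1] == 0L) &
            !(gt_mother[p1] == 2L & gt_father[p1] == 2L)
  ok[p2] <- gt_mother[p2] >= 1L & gt_father[p2] >= 1L
  ok
}

#' Apply the Mendelian filter to a trio genotype table
#'
#' Removes rows with a missing genotype in any trio member or with a
#' Mendelian error.
#'
#' @param trios Long-format trio genotype `data.table`
#'   (see [read_trio_genotypes()]).
#' @return The filtered table (a new `data.table`).
#' @export
mendelian_filter <- function(trios) {
  trios <- data.table::as.data.table(trios)
  trios[mendelian_keep(gt_proband, gt_mother, gt_father)]
}

#' Detect observed biallelic genotypes
#'
#' Scans Mendelian-filtered trio genotypes for biallelic genotypes per gene
#' and class pair: homozygous-alternate proband genotypes, and compound
#' heterozygotes in which the proband demonstrably inherited at least one
#' heterozygous variant of the relevant class from each parent (distinct
#' variants). A heterozygous variant's parental origin is unambiguous iff
#' exactly one parent can have contributed the alternate allele; a variant
#' with ambiguous origin never establishes a side on its own, but may pair
#' with an unambiguous opposite-side variant when a consistent phase
#' assignment puts the two in trans.
#'
#' Only autosomal variants are considered; a homozygous genotype of class c
#' yields a c/c call (a homozygous functional variant never combines with a
#' heterozygous LoF into LoF/functional).
#'
#' @param trios Mendelian-filtered long-format trio genotypes.
#' @param variants Classified variant table (with `class`; see
#'   [classify_variants()]). Variants of class `excluded` are ignored.
#' @return A `data.table` of calls: `trio_id`, `gene`, `class_pair`,
#'   `mechanism` (`homozygous` or `compound_het`), `variant_ids` (candidate
#'   contributing variants, comma-separated). Possibly several class pairs
#'   per trio and gene; see [most_severe_dedup()].
#' @export
detect_biallelic <- function(trios, variants) {
  trios <- data.table::as.data.table(trios)
  variants <- data.table::as.data.table(variants)
  if (!"class" %in% names(variants))
    stop("variants must carry a 'class' column; run classify_variants() first")
  vcols <- intersect(c("variant_id", "gene", "class", "chrom"), names(variants))
  m <- merge(trios, variants[, vcols, with = FALSE], by = "variant_id")
  if ("chrom" %in% names(m))
    m <- m[!chrom %in% c("X", "chrX", "Y", "chrY")]
  m <- m[class %in% c("LoF", "functional", "synonymous_control")]
  empty <- data.table::data.table(
    trio_id = character(), gene = character(), class_pair = character(),
    mechanism = character(), variant_ids = character()
  )
  if (nrow(m) == 0) return(empty)

  sides <- transmission_sides(m$gt_proband, m$gt_mother, m$gt_father)
  m[, `:=`(hom = gt_proband == 2L,
           fm = sides$forced_m, fp = sides$forced_p,
           cm = sides$can_m, cp = sides$can_p)]
  agg <- m[hom | cm | cp,
           .(n_hom = sum(hom), nfm = sum(fm), nfp = sum(fp),
             ncm = sum(cm), ncp = sum(cp),
             ids = paste(variant_id, collapse = ",")),
           by = .(trio_id, gene, class)]
  if (nrow(agg) == 0) return(empty)

  wide <- data.table::dcast(
    agg, trio_id + gene ~ class,
    value.var = list("n_hom", "nfm", "nfp", "ncm", "ncp", "ids"),
    fill = 0
  )
  for (cl in c("LoF", "functional", "synonymous_control")) {
    for (v in c("n_hom", "nfm", "nfp", "ncm", "ncp", "ids")) {
      col <- paste0(v, "_", cl)
      if (!col %in% names(wide))
        wide[[col]] <- if (v == "ids") "" else 0L
    }
  }
  g <- function(v, cl) wide[[paste0(v, "_", cl)]]
  # compound het between classes c1 and c2: an unambiguous variant on one
  # side plus a (possibly ambiguous) opposite-side partner of the other class
  comphet <- function(c1, c2) {
    (g("nfm", c1) > 0 & g("ncp", c2) > 0) |
    (g("nfp", c1) > 0 & g("ncm", c2) > 0) |
    (g("nfm", c2) > 0 & g("ncp", c1) > 0) |
    (g("nfp", c2) > 0 & g("ncm", c1) > 0)
  }
  join_ids <- function(c1, c2) {
    ids <- paste(g("ids", c1), g("ids", c2), sep = ",")
    if (c1 == c2) ids <- g("ids", c1)
    gsub("^,|,$", "", ids)
  }
  calls <- list()
  add_calls <- function(c1, c2) {
    is_hom <- if (c1 == c2) g("n_hom", c1) > 0 else rep(FALSE, nrow(wide))
    is_ch <- comphet(c1, c2)
    hit <- is_hom | is_ch
    if (!any(hit)) return(NULL)
    data.table::data.table(
      trio_id = wide$trio_id[hit], gene = wide$gene[hit],
      class_pair = pair_name(c1, c2),
      mechanism = ifelse(is_hom[hit], "homozygous", "compound_het"),
      variant_ids = join_ids(c1, c2)[hit]
    )
  }
  calls <- list(
    add_calls("LoF", "LoF"),
    add_calls("LoF", "functional"),
    add_calls("functional", "functional"),
    add_calls("synonymous_control", "synonymous_control")
  )
  out <- data.table::rbindlist(calls[!vapply(calls, is.null, TRUE)])
  if (nrow(out) == 0) return(empty)
  data.table::setkey(out, trio_id, gene, class_pair)
  out[]
}

#' Deduplicate to the most severe call per trio and gene
#'
#' If a trio has several damaging biallelic genotypes in the same gene, only
#' the most severe class pair is counted, with severity
#' LoF/LoF > LoF/functional > functional/functional. The
#' synonymous/synonymous control class is tabulated independently and never
#' competes with the damaging classes.
#'
#' Idempotent and order-independent.
#'
#' @param calls Output of [detect_biallelic()].
#' @return A `data.table` with at most one damaging call and one synonymous
#'   call per (trio, gene).
#' @export
most_severe_dedup <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0) return(calls)
  syn <- calls[class_pair == "synonymous_synonymous"]
  syn <- unique(syn, by = c("trio_id", "gene", "class_pair"))
  dmg <- calls[class_pair %in% names(CLASS_SEVERITY)]
  if (nrow(dmg)) {
    dmg[, rank := CLASS_SEVERITY[class_pair]]
    dmg <- dmg[order(rank), .SD[1], by = .(trio_id, gene)]
    dmg[, rank := NULL]
  }
  out <- data.table::rbindlist(list(dmg, syn), use.names = TRUE)
  data.table::setkey(out, trio_id, gene, class_pair)
  out[]
}

#' Tabulate observed biallelic genotype counts
#'
#' Counts, per (gene, class pair, stratum), the number of probands with at
#' least one biallelic genotype: O_{c,p,g}. Expects deduplicated calls, so a
#' trio contributes at most 1 to any cell.
#'
#' @param calls Output of [most_severe_dedup()].
#' @param meta Proband metadata with `trio_id` and `stratum`
#'   (see [read_proband_metadata()]); duplicated `trio_id` is an error.
#' @return A `data.table` with columns `gene`, `class_pair`, `stratum`, `O`
#'   (sparse: only non-zero cells).
#' @export
tabulate_observed <- function(calls, meta) {
  calls <- data.table::as.data.table(calls)
  meta <- data.table::as.data.table(meta)
  if (anyDuplicated(meta$trio_id)) stop("duplicate trio_id in metadata")
  if (nrow(calls) == 0)
    return(data.table::data.table(gene = character(), class_pair = character(),
                                  stratum = character(), O = integer()))
  if (anyDuplicated(calls[, .(trio_id, gene, class_pair)]))
    stop("calls must be deduplicated (one per trio, gene, class pair)")
  m <- merge(calls, meta[, .(trio_id, stratum)], by = "trio_id")
  if (nrow(m) < nrow(calls))
    stop("calls reference trio_id(s) absent from metadata")
  out <- m[, .(O = .N), by = .(gene, class_pair, stratum)]
  data.table::setkey(out, gene, class_pair, stratum)
  out[]
}
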