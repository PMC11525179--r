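# Transmission-based phase inference shared by the observed-genotype detector
# and the parental haplotype counter. With genotypes Mendelian-filtered, the
# consistency of assigning a child's heterozygous variant to the maternal or
# paternal transmitted haplotype is a purely per-variant condition: a parent's
# untransmitted haplotype can absorb any residual alleles, so no cross-variant
# coupling arises. This makes the "some consistent phase configuration"
# semantics of compound-het detection computable in closed form; tests verify
# the equivalence against a brute-force enumeration oracle.

# For a child-heterozygous variant:
#   can_m: some consistent phasing puts the child's alternate allele on the
#          maternal haplotype (mother carries >= 1 alt and father is not
#          homozygous-alternate, which would force paternal origin).
#   can_p: symmetric.
# forced_m = can_m & !can_p identifies an unambiguous maternal origin.
transmission_sides <- function(gt_proband, gt_mother, gt_father) {
  het <- !is.na(gt_proband) & gt_proband == 1L
  can_m <- het & gt_mother >= 1L & gt_father <= 1L
  can_p <- het & gt_father >= 1L & gt_mother <= 1L
  list(
    can_m = can_m, can_p = can_p,
    forced_m = can_m & !can_p, forced_p = can_p & !can_m
  )
}

#' Count a parent's class haplotypes in one gene
#'
#' For cumulative haplotype frequency estimation: given one unrelated,
#' unaffected parent's genotypes at the (already class- and gene-restricted)
#' variants, returns the number of that parent's haplotypes, 0/1/2, carrying
#' at least one variant of the class.
#'
#' Counting rules: a homozygous-alternate genotype counts two haplotypes; a
#' single heterozygous genotype counts one. With multiple heterozygous
#' variants, phase is inferred from transmission to the child: one haplotype
#' if they are in cis, two if in trans, and one if the phase is not clear.
#'
#' @param parent_gt Integer vector of the parent's genotypes (0/1/2) at the
#'   variants of one class in one gene.
#' @param child_gt Child genotypes at the same variants (0/1/2, NA = missing);
#'   used only for phasing. `NULL` (e.g. a frequency panel without offspring)
#'   leaves multi-het phase unresolved.
#' @param other_parent_gt The other parent's genotypes at the same variants,
#'   needed to attribute the child's heterozygous alleles; `NULL` as above.
#' @return Integer in `{0, 1, 2}`.
#' @export
count_parental_haplotypes <- function(parent_gt, child_gt = NULL,
                                      other_parent_gt = NULL) {
  parent_gt <- as.integer(parent_gt)
  if (any(parent_gt == 2L, na.rm = TRUE)) return(2L)
  hets <- which(!is.na(parent_gt) & parent_gt == 1L)
  if (length(hets) == 0L) return(0L)
  if (length(hets) == 1L) return(1L)
  if (is.null(child_gt) || is.null(other_parent_gt)) return(1L)  # phase unclear
  st <- transmission_status(parent_gt[hets], child_gt[hets],
                            other_parent_gt[hets])
  if (any(st == 1L) && any(st == -1L)) 2L else 1L
}

# Per-variant transmission status of a parent's heterozygous alternate allele:
# 1 = demonstrably on the transmitted haplotype, -1 = demonstrably on the
# untransmitted haplotype, 0 = unclear.
transmission_status <- function(parent_gt, child_gt, other_gt) {
  st <- integer(length(parent_gt))
  st[!is.na(child_gt) & child_gt == 0L] <- -1L
  st[!is.na(child_gt) & child_gt == 2L] <- 1L
  het <- !is.na(child_gt) & child_gt == 1L
  # child het: from this parent iff not attributable to the other parent
  st[het & other_gt == 0L] <- 1L
  st[het & other_gt == 2L] <- -1L
  st  # child het with other parent het, or child missing: unclear (0)
}
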