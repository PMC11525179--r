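# Independent brute-force oracles used across the test files. These are
# deliberately written as plain loops over enumerated configurations, sharing
# no code with the package's vectorized implementations.

# All Mendelian-consistent complete (proband, mother, father) genotype
# combinations at a single biallelic site, by direct allele enumeration:
# each parent transmits one allele drawn from its genotype.
oracle_mendelian_keep <- function(gp, gm, gf) {
  if (is.na(gp) || is.na(gm) || is.na(gf)) return(FALSE)
  allowed <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  for (am in allowed(gm)) for (af in allowed(gf)) {
    if (am + af == gp) return(TRUE)
  }
  FALSE
}

# Canonical class-pair name for the four tracked biallelic genotype classes;
# NA for untracked cross-class combinations (e.g. functional + synonymous).
oracle_pair_name <- function(c1, c2) {
  key <- c(LoF = "lof", functional = "functional",
           synonymous_control = "synonymous")
  if (c1 == c2) return(paste(key[[c1]], key[[c1]], sep = "_"))
  if (all(sort(c(c1, c2)) == c("LoF", "functional"))) return("lof_functional")
  NA_character_
}

# Exhaustive phase-enumeration oracle for biallelic genotype calls in one
# trio and gene. Enumerates every assignment of the child's heterozygous
# variants to the maternal/paternal transmitted haplotype, keeps the
# assignments consistent with the parental genotypes, and reports a
# compound-het class pair iff some consistent assignment puts two distinct
# variants of the right classes on opposite sides with at least one of the
# two having the same side in every consistent assignment (unambiguous
# origin). Homozygous-alternate variants yield within-class calls directly.
oracle_biallelic_calls <- function(classes, gp, gm, gf) {
  k <- length(classes)
  hets <- which(gp == 1L)
  homs <- which(gp == 2L)
  calls <- character()
  for (v in homs) calls <- c(calls, oracle_pair_name(classes[v], classes[v]))
  n_h <- length(hets)
  if (n_h >= 2) {
    sigma_grid <- expand.grid(rep(list(c("M", "P")), n_h),
                              stringsAsFactors = FALSE)
    valid <- matrix(NA, nrow(sigma_grid), n_h)
    keep <- logical(nrow(sigma_grid))
    for (i in seq_len(nrow(sigma_grid))) {
      ok <- TRUE
      for (j in seq_len(n_h)) {
        v <- hets[j]
        if (sigma_grid[i, j] == "M") {
          ok <- ok && gm[v] >= 1L && gf[v] <= 1L
        } else {
          ok <- ok && gf[v] >= 1L && gm[v] <= 1L
        }
      }
      keep[i] <- ok
    }
    vs <- sigma_grid[keep, , drop = FALSE]
    if (nrow(vs)) {
      forced <- vapply(seq_len(n_h), function(j) {
        u <- unique(vs[[j]])
        if (length(u) == 1L) u else "ambiguous"
      }, "")
      for (i in seq_len(nrow(vs))) {
        for (j1 in seq_len(n_h)) for (j2 in seq_len(n_h)) {
          if (j1 == j2) next
          if (vs[i, j1] == "M" && vs[i, j2] == "P" &&
              (forced[j1] != "ambiguous" || forced[j2] != "ambiguous")) {
            calls <- c(calls,
                       oracle_pair_name(classes[hets[j1]], classes[hets[j2]]))
          }
        }
      }
    }
  }
  sort(unique(calls[!is.na(calls)]))
}

# Brute-force oracle for the parental haplotype count of one parent in one
# gene and class. Enumerates every phasing of the parent's heterozygous
# variants onto two haplotypes, every choice of transmitted haplotype, and
# every allele the other parent could have transmitted, keeps configurations
# consistent with the child's genotypes, and collects the possible values of
# "number of parent haplotypes carrying at least one variant". A unique value
# is returned as-is; if both 1 and 2 remain possible the phase is unclear and
# the count is 1.
oracle_parent_hap_count <- function(parent_gt, child_gt, other_gt) {
  k <- length(parent_gt)
  hets <- which(parent_gt == 1L)
  n_h <- length(hets)
  allowed <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  possible <- integer()
  phase_grid <- expand.grid(rep(list(c(1L, 2L)), n_h))  # hap of each het
  if (n_h == 0) phase_grid <- data.frame(row.names = 1)
  for (pi in seq_len(nrow(phase_grid))) {
    hap <- matrix(0L, 2, k)
    for (v in which(parent_gt == 2L)) hap[, v] <- 1L
    if (n_h) for (j in seq_len(n_h)) hap[phase_grid[pi, j], hets[j]] <- 1L
    for (t in 1:2) {  # transmitted haplotype
      ok <- TRUE
      for (v in seq_len(k)) {
        if (is.na(child_gt[v])) next  # missing child genotype: no constraint
        opts <- allowed(other_gt[v])
        if (!any(hap[t, v] + opts == child_gt[v])) { ok <- FALSE; break }
      }
      if (ok) possible <- c(possible, sum(rowSums(hap[, , drop = FALSE]) >= 1))
    }
  }
  possible <- unique(possible)
  if (length(possible) == 1L) return(possible)
  1L  # phase not clear
}

# High-precision independent Poisson upper tail by direct series summation.
oracle_poisson_tail <- function(o, e) {
  if (o == 0) return(1)
  total <- 0
  k <- o
  repeat {
    term <- exp(-e + k * log(e) - lgamma(k + 1))
    total <- total + term
    if (term < total * 1e-18 && k > e + 10) break
    k <- k + 1
    if (k > o + 2000) break
  }
  total
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  cummin_rev <- Inf
  for (i in m:1) {
    val <- p[o[i]] * m / i
    cummin_rev <- min(cummin_rev, val)
    q[o[i]] <- min(1, cummin_rev)
  }
  q
}

# All Mendelian-consistent complete genotype triples at one site.
mendelian_consistent_triples <- function() {
  g <- expand.grid(gp = 0:2, gm = 0:2, gf = 0:2)
  g[mapply(oracle_mendelian_keep, g$gp, g$gm, g$gf), ]
}

# Build a one-variant-table for synthetic variants used in oracle tests.
make_test_variants <- function(classes, gene = "G1") {
  consequence <- c(LoF = "stop_gained", functional = "missense_variant",
                   synonymous_control = "synonymous_variant")[classes]
  data.table::data.table(
    variant_id = sprintf("chr1:%d:A:T", seq_along(classes) * 100L),
    gene = gene,
    consequence = unname(consequence),
    lof_confidence = ifelse(classes == "LoF", "high", "not_applicable"),
    splice_score = 0,
    class = classes
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
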