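# Synthetic consanguineous trio cohorts: Mendelian-consistent genotypes with
# controlled per-gene haplotype frequencies, per-gene autozygosity realized
# as ROH intervals, an independent parent frequency panel, and injected
# causal recessive burden with truth labels.
#
# Toy genome: one chromosome, one 1 Mb block per gene; the gene body occupies
# 20 kb in the middle of its block and an autozygous trio's ROH covers the
# whole block. F_ROH is the fraction of blocks autozygous, so the mean F_ROH
# of a stratum equals its per-gene autozygosity probability.

GENE_BLOCK <- 1e6L
GENE_START_OFFSET <- 450000L
GENE_WIDTH <- 20000L

#' Default per-gene variant pool
#'
#' Each gene carries 2 LoF variants (per-haplotype frequency 0.001), 3
#' functional (missense) variants (0.003 each) and 3 synonymous variants
#' (0.003 each), giving cumulative class haplotype frequencies of roughly
#' 0.2% (LoF) and 0.9% (functional, synonymous) - the scale expected after
#' restricting to variants with MAF <= 0.005.
#'
#' @param n_genes Number of genes.
#' @param lof_freq,functional_freq,synonymous_freq Per-variant per-haplotype
#'   frequencies.
#' @param n_lof,n_functional,n_synonymous Variants per gene and class.
#' @return A `data.table` (gene, variant_id, class, freq, chrom, pos).
#' @export
default_gene_pool <- function(n_genes = 60,
                              lof_freq = 0.001, functional_freq = 0.003,
                              synonymous_freq = 0.003,
                              n_lof = 2, n_functional = 3, n_synonymous = 3) {
  per_gene <- data.table::data.table(
    class = rep(c("LoF", "functional", "synonymous_control"),
                c(n_lof, n_functional, n_synonymous)),
    freq = rep(c(lof_freq, functional_freq, synonymous_freq),
               c(n_lof, n_functional, n_synonymous))
  )
  pool <- per_gene[rep(seq_len(nrow(per_gene)), n_genes)]
  pool[, gene := rep(sprintf("G%03d", seq_len(n_genes)), each = nrow(per_gene))]
  gi <- as.integer(factor(pool$gene, levels = unique(pool$gene)))
  within <- rep(seq_len(nrow(per_gene)), n_genes)
  pool[, chrom := "chr1"]
  pool[, pos := (gi - 1L) * GENE_BLOCK + GENE_START_OFFSET + within * 100L]
  pool[, variant_id := paste(chrom, pos, "A", "T", sep = ":")]
  data.table::setcolorder(pool, c("gene", "variant_id", "class", "freq",
                                  "chrom", "pos"))
  pool[]
}

gene_intervals <- function(gene_pool) {
  genes <- unique(gene_pool$gene)
  data.table::data.table(
    gene = genes,
    chrom = "chr1",
    start = (seq_along(genes) - 1L) * GENE_BLOCK + GENE_START_OFFSET,
    end = (seq_along(genes) - 1L) * GENE_BLOCK + GENE_START_OFFSET + GENE_WIDTH
  )
}

genes_as_granges <- function(genes_dt) {
  gr <- GenomicRanges::GRanges(
    genes_dt$chrom, IRanges::IRanges(genes_dt$start + 1L, genes_dt$end)
  )
  gr$name <- genes_dt$gene
  gr
}

roh_as_granges <- function(roh_dt) {
  if (nrow(roh_dt) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$name <- character()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    roh_dt$chrom, IRanges::IRanges(roh_dt$start + 1L, roh_dt$end)
  )
  gr$name <- roh_dt$trio_id
  gr
}

#' Simulation configuration
#'
#' Defines the generative conditions for a synthetic stratified trio cohort.
#' The defaults emulate a two-stratum design: a large, low-autozygosity
#' stratum (2,000 trios, per-gene autozygosity probability 0.001, as in a
#' large European-ancestry group) and a smaller consanguineous stratum
#' (500 trios, autozygosity 0.05, as in a Pakistani-ancestry group with
#' customary cousin marriage).
#'
#' @param seed RNG seed; the same config and seed give identical cohorts.
#' @param strata List of `list(label, n_trios, n_panel, a_gene)` entries:
#'   stratum label, trio count, independent frequency-panel parent count,
#'   and per-gene autozygosity probability.
#' @param gene_pool Per-gene variant pool, see [default_gene_pool()].
#' @param theta Injected attributable fraction: a scalar applied to every
#'   stratum, or a named vector keyed by stratum label.
#' @param target_genes Genes receiving injected causal genotypes; default
#'   the first 10 genes of the pool (the synthetic "known disease gene"
#'   list).
#' @param mechanism_split Probability an injected genotype is homozygous
#'   (vs compound heterozygous).
#' @param clinvar_plp_share Fraction of distinct injected causal variants
#'   flagged pathogenic/likely-pathogenic.
#' @param diagnosed_share Fraction of injected-causal probands marked
#'   diagnosed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              strata = list(
                                list(label = "EUR_like", n_trios = 2000L,
                                     n_panel = 2000L, a_gene = 0.001),
                                list(label = "SAS_like", n_trios = 500L,
                                     n_panel = 500L, a_gene = 0.05)
                              ),
                              gene_pool = default_gene_pool(),
                              theta = 0,
                              target_genes = NULL,
                              mechanism_split = 0.5,
                              clinvar_plp_share = 0.66,
                              diagnosed_share = 0.5) {
  stopifnot(all(theta >= 0), all(theta <= 1),
            mechanism_split >= 0, mechanism_split <= 1,
            clinvar_plp_share >= 0, clinvar_plp_share <= 1,
            diagnosed_share >= 0, diagnosed_share <= 1,
            all(gene_pool$freq >= 0 & gene_pool$freq <= 1))
  for (s in strata)
    stopifnot(s$a_gene >= 0, s$a_gene <= 1, s$n_trios >= 1)
  if (is.null(target_genes))
    target_genes <- head(unique(gene_pool$gene), 10)
  structure(
    list(seed = as.integer(seed), strata = strata, gene_pool = gene_pool,
         theta = theta, target_genes = target_genes,
         mechanism_split = mechanism_split,
         clinvar_plp_share = clinvar_plp_share,
         diagnosed_share = diagnosed_share),
    class = "simulation_config"
  )
}

# Sparse carrier draw: indices of carrying haplotypes among n_haps.
draw_carriers <- function(n_haps, freq) {
  n_c <- stats::rbinom(1L, n_haps, freq)
  if (n_c == 0L) integer() else sample.int(n_haps, n_c)
}

#' Simulate an independent parent frequency panel
#'
#' Each panel parent is two independent population haplotypes; each
#' haplotype carries each pool variant independently with its frequency.
#'
#' @param n_parents Number of panel parents.
#' @param gene_pool Variant pool (see [default_gene_pool()]).
#' @param id_prefix Prefix for parent ids.
#' @return A sparse long `data.table` (parent_id, variant_id, gt); parents
#'   with no rare allele have no rows.
#' @export
simulate_parent_panel <- function(n_parents, gene_pool,
                                  id_prefix = "panel") {
  n_haps <- 2L * n_parents
  rows <- lapply(seq_len(nrow(gene_pool)), function(i) {
    hap <- draw_carriers(n_haps, gene_pool$freq[i])
    if (!length(hap)) return(NULL)
    data.table::data.table(parent = (hap - 1L) %/% 2L + 1L,
                           variant_id = gene_pool$variant_id[i])
  })
  rows <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(rows) == 0)
    return(data.table::data.table(parent_id = character(),
                                  variant_id = character(), gt = integer()))
  out <- rows[, .(gt = .N), by = .(parent, variant_id)]
  out[, parent_id := sprintf("%s_%06d", id_prefix, parent)]
  out[, parent := NULL]
  data.table::setcolorder(out, c("parent_id", "variant_id", "gt"))
  out[]
}

# Simulate the trios of one stratum: genotypes and ROH intervals.
# For each gene independently: with probability a_gene the trio is autozygous
# there (a shared population haplotype is planted in both parents and
# transmitted by both, and an ROH covering the gene block is emitted);
# otherwise each parent transmits one of two independent haplotypes.
simulate_stratum_trios <- function(n_trios, gene_pool, a_gene, trio_ids) {
  genes <- unique(gene_pool$gene)
  gdt <- gene_intervals(gene_pool)
  gt_rows <- vector("list", length(genes))
  roh_rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    gpool <- gene_pool[gene == genes[gi]]
    z <- stats::runif(n_trios) < a_gene
    t_m <- sample.int(2L, n_trios, replace = TRUE)
    t_f <- sample.int(2L, n_trios, replace = TRUE)
    t_m[z] <- 1L
    t_f[z] <- 1L  # the shared haplotype occupies maternal slot 1 / paternal slot 3
    carr <- lapply(seq_len(nrow(gpool)), function(i) {
      hap <- draw_carriers(4L * n_trios, gpool$freq[i])
      if (!length(hap)) return(NULL)
      data.table::data.table(
        trio = (hap - 1L) %% n_trios + 1L,
        slot = (hap - 1L) %/% n_trios + 1L,
        variant_id = gpool$variant_id[i]
      )
    })
    carr <- data.table::rbindlist(carr[!vapply(carr, is.null, TRUE)])
    if (any(z))
      roh_rows[[gi]] <- data.table::data.table(
        trio_id = trio_ids[which(z)],
        chrom = gdt$chrom[gi],
        start = (gi - 1L) * GENE_BLOCK,
        end = gi * GENE_BLOCK
      )
    if (nrow(carr) == 0) next
    # autozygosity: paternal slot 3 mirrors maternal slot 1
    auto <- z[carr$trio]
    carr <- carr[!(auto & slot == 3L)]
    shared <- carr[z[trio] & slot == 1L]
    if (nrow(shared)) {
      shared <- data.table::copy(shared)[, slot := 3L]
      carr <- data.table::rbindlist(list(carr, shared))
    }
    carr[, transmitted := (slot == t_m[trio]) | (slot == t_f[trio] + 2L)]
    gt <- carr[, .(
      gt_mother = sum(slot <= 2L),
      gt_father = sum(slot >= 3L),
      gt_proband = sum(transmitted)
    ), by = .(trio, variant_id)]
    gt[, trio_id := trio_ids[trio]]
    gt[, trio := NULL]
    gt_rows[[gi]] <- gt
  }
  trios <- data.table::rbindlist(gt_rows[!vapply(gt_rows, is.null, TRUE)])
  if (nrow(trios) == 0)
    trios <- data.table::data.table(trio_id = character(),
                                    variant_id = character(),
                                    gt_proband = integer(),
                                    gt_mother = integer(),
                                    gt_father = integer())
  data.table::setcolorder(trios, c("trio_id", "variant_id", "gt_proband",
                                   "gt_mother", "gt_father"))
  roh <- data.table::rbindlist(roh_rows[!vapply(roh_rows, is.null, TRUE)])
  if (is.null(roh) || nrow(roh) == 0)
    roh <- data.table::data.table(trio_id = character(), chrom = character(),
                                  start = integer(), end = integer())
  list(trios = trios, roh = roh)
}

#' Simulate a stratified trio cohort
#'
#' Generates, per stratum, Mendelian-consistent trio genotypes under the
#' generative model in which the within-class biallelic genotype rate is
#' exactly (1 - a) f^2 + a f, emits ROH intervals realizing the per-gene
#' autozygosity, simulates an independent parent frequency panel, and (if
#' `theta > 0`) injects causal damaging biallelic genotypes with truth
#' labels via [inject_causal()].
#'
#' @param config A [simulation_config()].
#' @return An object of class `rb_cohort`: list with `variants` (annotated
#'   variant table), `trios`, `meta`, `roh`, `genes`, `panel`, `panel_meta`,
#'   `truth`, `genome_length`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pool <- config$gene_pool
  genes_dt <- gene_intervals(pool)
  trios_l <- list(); roh_l <- list(); meta_l <- list()
  panel_l <- list(); panel_meta_l <- list()
  for (s in config$strata) {
    trio_ids <- sprintf("%s_T%05d", s$label, seq_len(s$n_trios))
    sim <- simulate_stratum_trios(s$n_trios, pool, s$a_gene, trio_ids)
    trios_l[[s$label]] <- sim$trios
    roh_l[[s$label]] <- sim$roh
    meta_l[[s$label]] <- data.table::data.table(
      trio_id = trio_ids, stratum = s$label, cohort = "SIM",
      diagnosed = FALSE,
      sex = sample(c("F", "M"), s$n_trios, replace = TRUE),
      mother_eligible = TRUE, father_eligible = TRUE
    )
    panel <- simulate_parent_panel(s$n_panel, pool,
                                   id_prefix = paste0(s$label, "_P"))
    panel_l[[s$label]] <- panel
    panel_meta_l[[s$label]] <- data.table::data.table(
      parent_id = sprintf("%s_P_%06d", s$label, seq_len(s$n_panel)),
      stratum = s$label
    )
  }
  variants <- pool[, .(
    variant_id, gene, consequence = data.table::fifelse(
      class == "LoF", "stop_gained",
      data.table::fifelse(class == "functional", "missense_variant",
                          "synonymous_variant")),
    lof_confidence = data.table::fifelse(class == "LoF", "high",
                                         "not_applicable"),
    splice_score = 0, ref_hom_count = 0L, clinvar_plp = FALSE,
    chrom, pos, ref = "A", alt = "T", true_class = class, freq
  )]
  for (s in config$strata)
    variants[[paste0("stratum:", s$label)]] <- variants$freq
  variants[["ref:gnomAD"]] <- variants$freq

  cohort <- structure(
    list(
      variants = variants,
      trios = data.table::rbindlist(trios_l),
      meta = data.table::rbindlist(meta_l),
      roh = data.table::rbindlist(roh_l),
      genes = genes_dt,
      panel = data.table::rbindlist(panel_l),
      panel_meta = data.table::rbindlist(panel_meta_l),
      truth = NULL,
      genome_length = nrow(genes_dt) * GENE_BLOCK,
      config = config
    ),
    class = "rb_cohort"
  )
  cohort$truth <- data.table::data.table(
    trio_id = cohort$meta$trio_id, injected = FALSE,
    gene = NA_character_, mechanism = NA_character_
  )
  if (any(config$theta > 0))
    cohort <- inject_causal(cohort, config$theta, config$target_genes,
                            mechanism_split = config$mechanism_split,
                            clinvar_plp_share = config$clinvar_plp_share,
                            diagnosed_share = config$diagnosed_share)
  cohort
}

#' @export
print.rb_cohort <- function(x, ...) {
  cat("<rb_cohort>", nrow(x$meta), "trios,",
      length(unique(x$meta$stratum)), "strata,",
      nrow(x$genes), "genes,", nrow(x$variants), "variants\n")
  if (!is.null(x$truth))
    cat("  injected causal trios:", sum(x$truth$injected), "\n")
  invisible(x)
}

#' Inject causal biallelic genotypes
#'
#' Overwrites the genotypes of `round(theta * n_trios)` trios per stratum at
#' pool variants of a target gene with a forced damaging biallelic genotype
#' (homozygous LoF with probability `mechanism_split`, otherwise a
#' LoF + functional compound heterozygote with one variant inherited from
#' each parent), preserving Mendelian consistency. Injected trios are
#' labelled in `truth`; a fraction of the distinct causal variants used is
#' flagged ClinVar P/LP, and a fraction of injected probands is marked
#' diagnosed.
#'
#' Uses the current RNG state (call inside a seeded context, or rely on
#' [simulate_cohort()] which injects under the config seed).
#'
#' @param cohort An `rb_cohort`.
#' @param theta Injected attributable fraction in \[0, 1\]: scalar, or a
#'   named per-stratum vector.
#' @param target_genes Genes to inject into (cycled over injected trios).
#' @param mechanism_split,clinvar_plp_share,diagnosed_share See
#'   [simulation_config()].
#' @return The modified cohort.
#' @export
inject_causal <- function(cohort, theta, target_genes,
                          mechanism_split = 0.5, clinvar_plp_share = 0.66,
                          diagnosed_share = 0.5) {
  stopifnot(inherits(cohort, "rb_cohort"), all(theta >= 0))
  if (any(theta > 1)) stop("theta must be <= 1")
  if (all(theta == 0)) return(cohort)
  pool <- cohort$config$gene_pool
  target_genes <- intersect(target_genes, unique(pool$gene))
  stopifnot(length(target_genes) >= 1)
  lof_by_gene <- pool[class == "LoF", .(variant_id = variant_id[1]), by = gene]
  fun_by_gene <- pool[class == "functional", .(variant_id = variant_id[1]),
                      by = gene]
  theta_for <- function(label) {
    if (is.null(names(theta))) return(theta[1])
    if (label %in% names(theta)) theta[[label]] else 0
  }
  picks <- list()
  for (s in cohort$config$strata) {
    ids <- cohort$meta[stratum == s$label]$trio_id
    m <- round(theta_for(s$label) * length(ids))
    if (m == 0) next
    picks[[s$label]] <- sample(ids, m)
  }
  picked <- unlist(picks, use.names = FALSE)
  if (is.null(picked) || length(picked) == 0) return(cohort)
  inj <- data.table::data.table(
    trio_id = picked,
    gene = rep_len(target_genes, length(picked)),
    mechanism = data.table::fifelse(
      stats::runif(length(picked)) < mechanism_split,
      "homozygous", "compound_het")
  )
  inj <- merge(inj, lof_by_gene, by = "gene")
  data.table::setnames(inj, "variant_id", "lof_variant")
  inj <- merge(inj, fun_by_gene, by = "gene")
  data.table::setnames(inj, "variant_id", "fun_variant")

  forced <- data.table::rbindlist(list(
    inj[mechanism == "homozygous",
        .(trio_id, variant_id = lof_variant,
          gt_proband = 2L, gt_mother = 1L, gt_father = 1L)],
    inj[mechanism == "compound_het",
        .(trio_id, variant_id = lof_variant,
          gt_proband = 1L, gt_mother = 1L, gt_father = 0L)],
    inj[mechanism == "compound_het",
        .(trio_id, variant_id = fun_variant,
          gt_proband = 1L, gt_mother = 0L, gt_father = 1L)]
  ))
  trios <- cohort$trios
  trios <- trios[!forced[, .(trio_id, variant_id)], on = c("trio_id", "variant_id")]
  cohort$trios <- data.table::rbindlist(list(trios, forced), use.names = TRUE)

  used <- unique(c(inj$lof_variant, inj[mechanism == "compound_het"]$fun_variant))
  n_flag <- round(clinvar_plp_share * length(used))
  if (n_flag > 0) {
    flagged <- sample(used, n_flag)
    cohort$variants[variant_id %in% flagged, clinvar_plp := TRUE]
  }
  diagnosed_ids <- inj$trio_id[stats::runif(nrow(inj)) < diagnosed_share]
  cohort$meta[trio_id %in% diagnosed_ids, diagnosed := TRUE]
  cohort$truth[inj, on = "trio_id",
               `:=`(injected = TRUE, gene = i.gene, mechanism = i.mechanism)]
  cohort
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits the exact input dialects the readers consume: `variants.tsv`,
#' `trios.tsv`, `meta.tsv`, `roh.bed` (name = trio id), `genes.bed`
#' (name = gene), `panel.tsv`, `panel_meta.tsv`, `truth.tsv` and
#' `cohort_info.tsv` (genome length, seed). [read_cohort()] reconstructs the
#' cohort.
#'
#' @param cohort An `rb_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
emit_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(x) file.path(dir, x)
  write_variant_table(cohort$variants, pth("variants.tsv"))
  write_trio_genotypes(cohort$trios, pth("trios.tsv"))
  write_proband_metadata(cohort$meta, pth("meta.tsv"))
  write_bed(roh_as_granges(cohort$roh), pth("roh.bed"))
  write_bed(genes_as_granges(cohort$genes), pth("genes.bed"))
  data.table::fwrite(cohort$panel, pth("panel.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$panel_meta, pth("panel_meta.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(cohort$truth, pth("truth.tsv"), sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(
    data.table::data.table(param = c("genome_length", "seed"),
                           value = c(cohort$genome_length, cohort$config$seed)),
    pth("cohort_info.tsv"), sep = "\t", quote = FALSE
  )
  invisible(dir)
}

#' @rdname emit_cohort
#' @export
read_cohort <- function(dir) {
  pth <- function(x) file.path(dir, x)
  info <- data.table::fread(pth("cohort_info.tsv"))
  genes_gr <- read_bed(pth("genes.bed"))
  genes <- data.table::data.table(
    gene = genes_gr$name,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr)
  )
  roh_gr <- read_bed(pth("roh.bed"))
  roh <- data.table::data.table(
    trio_id = if (length(roh_gr)) roh_gr$name else character(),
    chrom = as.character(GenomicRanges::seqnames(roh_gr)),
    start = GenomicRanges::start(roh_gr) - 1L,
    end = GenomicRanges::end(roh_gr)
  )
  structure(
    list(
      variants = read_variant_table(pth("variants.tsv")),
      trios = read_trio_genotypes(pth("trios.tsv")),
      meta = read_proband_metadata(pth("meta.tsv")),
      roh = roh, genes = genes,
      panel = data.table::fread(pth("panel.tsv"),
                                colClasses = list(character = c("parent_id", "variant_id"))),
      panel_meta = data.table::fread(pth("panel_meta.tsv"),
                                     colClasses = list(character = c("parent_id", "stratum"))),
      truth = data.table::fread(pth("truth.tsv"),
                                colClasses = list(character = "trio_id")),
      genome_length = as.numeric(info[param == "genome_length"]$value),
      config = NULL
    ),
    class = "rb_cohort"
  )
}
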