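# Data model and file IO: annotated variant tables (TSV or VCF dialect),
# long-format trio genotypes, BED intervals, proband metadata, and the
# per-cohort summary-exchange format that supports pooling observed/expected
# counts across cohorts without sharing genotypes.

SUMMARY_SCHEMA_VERSION <- "rburden_cohort_summary_v1"

GT_LEVELS <- c(0L, 1L, 2L)
MISSING_TOKENS <- c(".", "NA", "missing", "")

CLASS_PAIRS <- c("lof_lof", "lof_functional", "functional_functional",
                 "synonymous_synonymous")
DAMAGING_PAIRS <- CLASS_PAIRS[1:3]

parse_variant_id <- function(variant_id) {
  parts <- data.table::tstrsplit(variant_id, ":", fixed = TRUE)
  if (length(parts) != 4L)
    stop("variant_id must be a 'chrom:pos:ref:alt' key")
  list(chrom = parts[[1]], pos = as.integer(parts[[2]]),
       ref = parts[[3]], alt = parts[[4]])
}

validate_variants <- function(dt) {
  required <- c("variant_id", "gene", "consequence", "lof_confidence",
                "splice_score", "ref_hom_count", "clinvar_plp")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(grepl(",", dt$alt, fixed = TRUE))
  if (length(bad))
    stop("multi-allelic records must be decomposed before input; offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  freq_cols <- grep("^(stratum|ref):", names(dt), value = TRUE)
  for (col in freq_cols) {
    v <- dt[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop(sprintf("frequency column '%s' outside [0,1] at row(s): %s",
                   col, paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(is.na(dt$ref_hom_count) | dt$ref_hom_count < 0)
  if (length(bad))
    stop("ref_hom_count must be a non-negative integer; offending row(s): ",
         paste(head(bad, 5), collapse = ", "))
  invisible(dt)
}

#' Read an annotated variant table
#'
#' Reads the analysis variant annotation table either from TSV (columns
#' `variant_id`, `gene`, `consequence`, `lof_confidence`, `splice_score`,
#' `stratum:<p>` local parental allele-frequency columns, `ref:<pop>`
#' reference-population frequency columns, `ref_hom_count`, `clinvar_plp`)
#' or from a VCF dialect in which the same fields are INFO keys
#' (`gene`, `consequence`, `lof_confidence`, `splice_score`,
#' `stratum_<p>`, `ref_<pop>`, `ref_hom_count`, and presence/absence flag
#' `clinvar_plp`). `variant_id` is the `chrom:pos:ref:alt` key; positions are
#' 1-based as in VCF. Multi-allelic records must be pre-decomposed and are
#' rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A `data.table` with one validated row per variant, including
#'   parsed `chrom`, `pos`, `ref`, `alt` columns.
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            check.names = FALSE, na.strings = c("NA", "."))
  } else {
    dt <- read_variant_vcf(path)
  }
  required <- c("variant_id", "gene", "consequence", "lof_confidence",
                "splice_score", "ref_hom_count", "clinvar_plp")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[, c("chrom", "pos", "ref", "alt") := parse_variant_id(variant_id)]
  dt[, ref_hom_count := as.integer(ref_hom_count)]
  dt[, clinvar_plp := as.logical(clinvar_plp)]
  validate_variants(dt)
  data.table::setcolorder(dt, c("variant_id", "chrom", "pos", "ref", "alt"))
  dt[]
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_ids <- vcfR::queryMETA(vcf, element = "INFO")
  info_ids <- vapply(info_ids, function(x) sub("^INFO=ID=", "", x[1]), "")
  dt <- data.table::data.table(
    variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  )
  numeric_keys <- c("splice_score", "ref_hom_count")
  plain_keys <- c("gene", "consequence", "lof_confidence", "splice_score",
                  "ref_hom_count", "clinvar_plp")
  for (id in info_ids) {
    col <- id
    if (!id %in% plain_keys) {
      col <- sub("^stratum_", "stratum:", col)
      col <- sub("^ref_", "ref:", col)
    }
    if (id == "clinvar_plp") {
      data.table::set(dt, j = col,
                      value = grepl("(^|;)clinvar_plp(;|$)", vcf@fix[, "INFO"]))
    } else {
      vals <- vcfR::extract.info(vcf, element = id)
      numeric <- id %in% numeric_keys || grepl("^(stratum|ref):", col)
      data.table::set(dt, j = col, value = if (numeric) as.numeric(vals) else vals)
    }
  }
  if (!"clinvar_plp" %in% names(dt))
    data.table::set(dt, j = "clinvar_plp", value = FALSE)
  dt
}

#' Write an annotated variant table as TSV
#'
#' @param variants Variant `data.table` (from [read_variant_table()] or
#'   [simulate_cohort()]).
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  out <- data.table::as.data.table(variants)
  drop <- intersect(c("chrom", "pos", "ref", "alt"), names(out))
  out <- out[, setdiff(names(out), drop), with = FALSE]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read long-format trio genotypes
#'
#' Expects a TSV with columns `trio_id`, `variant_id`, `gt_proband`,
#' `gt_mother`, `gt_father`; genotypes are unphased alternate-allele counts
#' in `{0, 1, 2}`, with `.`/`NA`/`missing` for a missing call. Phase is never
#' read from input; it is inferred downstream from transmission only.
#'
#' Rows absent from the table are implicitly homozygous reference: the
#' observed-genotype machinery only needs rows where some trio member carries
#' an alternate allele.
#'
#' @param path File path.
#' @return A `data.table` with integer genotype columns (NA = missing).
#' @export
read_trio_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = MISSING_TOKENS,
                          colClasses = list(character = c("trio_id", "variant_id")))
  required <- c("trio_id", "variant_id", "gt_proband", "gt_mother", "gt_father")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("trio genotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("gt_proband", "gt_mother", "gt_father")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(!is.na(dt[[col]]) & (is.na(v) | !(v %in% GT_LEVELS)))
    if (length(bad))
      stop(sprintf("column '%s' has genotypes outside {0,1,2,missing} at row(s): %s",
                   col, paste(head(bad, 5), collapse = ", ")))
    data.table::set(dt, j = col, value = v)
  }
  dt[]
}

#' Write long-format trio genotypes as TSV
#' @param trios Trio genotype `data.table`.
#' @param path Output path.
#' @export
write_trio_genotypes <- function(trios, path) {
  data.table::fwrite(data.table::as.data.table(trios), path, sep = "\t",
                     na = ".", quote = FALSE)
  invisible(path)
}

#' Read proband/trio metadata
#'
#' TSV with columns `trio_id`, `stratum`, `cohort`, `diagnosed`, `sex` and
#' optional `froh` (fraction of the autosomal genome in runs of homozygosity),
#' `mother_eligible`, `father_eligible` (whether each parent counts as
#' unrelated and unaffected for frequency estimation; default `TRUE`).
#'
#' @param path File path.
#' @return A `data.table`, one row per trio.
#' @export
read_proband_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  required <- c("trio_id", "stratum", "cohort", "diagnosed", "sex")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(dt$trio_id))
    stop("duplicate trio_id in metadata")
  dt[, trio_id := as.character(trio_id)]
  dt[, diagnosed := as.logical(diagnosed)]
  if (!"mother_eligible" %in% names(dt)) dt[, mother_eligible := TRUE]
  if (!"father_eligible" %in% names(dt)) dt[, father_eligible := TRUE]
  dt[]
}

#' Write proband metadata as TSV
#' @param meta Metadata `data.table`.
#' @param path Output path.
#' @export
write_proband_metadata <- function(meta, path) {
  data.table::fwrite(data.table::as.data.table(meta), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3 (+ optional name column) with 0-based half-open coordinates,
#' converted to 1-based closed `GRanges`.
#'
#' @param path File path.
#' @return A `GRanges`; the 4th BED column, if present, becomes `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("BED file must have at least 3 columns")
  if (any(dt[[2]] >= dt[[3]]))
    stop("BED intervals must satisfy start < end")
  gr <- GenomicRanges::GRanges(
    dt[[1]], IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]])
  )
  if (ncol(dt) >= 4) gr$name <- as.character(dt[[4]])
  gr
}

#' Write a GRanges as BED (0-based half-open)
#' @param gr A `GRanges`; a `name` metadata column, if present, is written
#'   as the 4th BED column.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) dt[, name := gr$name]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a cohort summary
#'
#' The exchangeable unit of a federated analysis: per (gene, genotype class
#' pair, stratum) observed and expected biallelic genotype counts, plus
#' per-stratum sample sizes. Contains no individual-level data; summaries
#' from different cohorts can be merged by summation
#' ([merge_cohort_summaries()]).
#'
#' @param counts `data.table` with columns `gene`, `class_pair` (one of
#'   `lof_lof`, `lof_functional`, `functional_functional`,
#'   `synonymous_synonymous`), `stratum`, `O` (non-negative integer), `E`
#'   (non-negative).
#' @param strata `data.table` with columns `stratum`, `n_probands`,
#'   `n_parent_haplotypes`, `mean_froh`.
#' @return An object of class `cohort_summary`.
#' @export
cohort_summary <- function(counts, strata) {
  counts <- data.table::as.data.table(counts)
  strata <- data.table::as.data.table(strata)
  stopifnot(all(c("gene", "class_pair", "stratum", "O", "E") %in% names(counts)),
            all(c("stratum", "n_probands", "n_parent_haplotypes", "mean_froh")
                %in% names(strata)))
  if (any(counts$O < 0) || any(counts$O != round(counts$O)))
    stop("O must be a non-negative integer")
  if (any(counts$E < 0)) stop("E must be non-negative")
  if (!all(counts$class_pair %in% CLASS_PAIRS))
    stop("unknown class_pair value(s): ",
         paste(setdiff(counts$class_pair, CLASS_PAIRS), collapse = ", "))
  counts[, O := as.integer(O)]
  structure(
    list(version = SUMMARY_SCHEMA_VERSION, counts = counts[], strata = strata[]),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$version, "\n")
  cat("  strata:", nrow(x$strata),
      " probands:", sum(x$strata$n_probands), "\n")
  cat("  count cells:", nrow(x$counts),
      " genes:", length(unique(x$counts$gene)), "\n")
  invisible(x)
}

#' Write / read a cohort summary
#'
#' Plain-text, versioned exchange format: a header line carrying the schema
#' version, a strata section and a counts section. Reading a file with an
#' unknown schema version fails loudly.
#'
#' @param summary A [cohort_summary()].
#' @param path File path.
#' @return `write_cohort_summary` the path, invisibly;
#'   `read_cohort_summary` a `cohort_summary`.
#' @export
write_cohort_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#version\t", summary$version), con)
  writeLines("#strata", con)
  writeLines(paste(names(summary$strata), collapse = "\t"), con)
  if (nrow(summary$strata))
    writeLines(do.call(paste, c(summary$strata, sep = "\t")), con)
  writeLines("#counts", con)
  writeLines(paste(names(summary$counts), collapse = "\t"), con)
  if (nrow(summary$counts))
    writeLines(do.call(paste, c(summary$counts, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_cohort_summary
#' @export
read_cohort_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!grepl("^#version\t", lines[1]))
    stop("not a cohort summary file (missing #version header)")
  version <- sub("^#version\t", "", lines[1])
  if (version != SUMMARY_SCHEMA_VERSION)
    stop(sprintf("unknown cohort summary schema version '%s' (expected '%s')",
                 version, SUMMARY_SCHEMA_VERSION))
  i_strata <- which(lines == "#strata")
  i_counts <- which(lines == "#counts")
  read_section <- function(block) {
    if (length(block) < 1) stop("malformed cohort summary section")
    data.table::fread(text = paste(block, collapse = "\n"), sep = "\t",
                      header = TRUE)
  }
  strata <- read_section(lines[(i_strata + 1):(i_counts - 1)])
  counts <- read_section(lines[(i_counts + 1):length(lines)])
  counts[, gene := as.character(gene)]
  counts[, stratum := as.character(stratum)]
  strata[, stratum := as.character(stratum)]
  cohort_summary(counts, strata)
}

#' Merge cohort summaries
#'
#' Pools observed and expected counts across cohorts by summing `O` and `E`
#' per (gene, class pair, stratum) cell, summing proband and parental
#' haplotype totals per stratum, and combining mean autozygosity as the
#' proband-weighted mean. Merging is associative and commutative.
#'
#' @param ... Two or more [cohort_summary()] objects (or a single list of them).
#' @return A merged `cohort_summary`.
#' @export
merge_cohort_summaries <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !inherits(args[[1]], "cohort_summary"))
    args <- args[[1]]
  stopifnot(length(args) >= 1, all(vapply(args, inherits, TRUE, "cohort_summary")))
  counts <- data.table::rbindlist(lapply(args, `[[`, "counts"))
  counts <- counts[, .(O = sum(O), E = sum(E)),
                   by = .(gene, class_pair, stratum)]
  strata <- data.table::rbindlist(lapply(args, `[[`, "strata"))
  strata <- strata[, .(
    n_probands = sum(n_probands),
    n_parent_haplotypes = sum(n_parent_haplotypes),
    mean_froh = sum(mean_froh * n_probands) / sum(n_probands)
  ), by = stratum]
  data.table::setkey(counts, gene, class_pair, stratum)
  cohort_summary(counts, strata)
}
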