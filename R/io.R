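# Plain-text interchange: minimal phased VCF, read/count TSVs, ASM BED and
# the truth JSON sidecar.

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits `genotypes.vcf` (minimal VCF v4.2, phased GT field), `reads.tsv`
#' (one row per read with `pos:allele` and `pos:state` lists),
#' `allelic_counts.tsv`, `pedigree.tsv`, `germline_libraries.tsv`,
#' `germline_region_calls.tsv` and `truth.json`.
#'
#' @param sim An [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_phased_vcf(sim$cohort$genotypes, sim$cohort$samples,
                   file.path(dir, "genotypes.vcf"))

  snp_str <- stats::aggregate(
    list(snps = paste0(sim$reads$read_snps$pos, ":",
                       sim$reads$read_snps$allele)),
    by = list(read_id = sim$reads$read_snps$read_id),
    FUN = paste, collapse = ",")
  cpg_str <- stats::aggregate(
    list(cpgs = paste0(sim$reads$read_cpgs$pos, ":",
                       sim$reads$read_cpgs$methylated)),
    by = list(read_id = sim$reads$read_cpgs$read_id),
    FUN = paste, collapse = ",")
  reads <- sim$reads$reads |>
    dplyr::left_join(snp_str, by = "read_id") |>
    dplyr::left_join(cpg_str, by = "read_id")
  readr::write_tsv(reads, file.path(dir, "reads.tsv"))
  readr::write_tsv(sim$rna$allelic_counts,
                   file.path(dir, "allelic_counts.tsv"))
  readr::write_tsv(sim$cohort$truth$pedigree, file.path(dir, "pedigree.tsv"))
  readr::write_tsv(sim$germline$libraries,
                   file.path(dir, "germline_libraries.tsv"))
  readr::write_tsv(sim$germline$region_calls,
                   file.path(dir, "germline_region_calls.tsv"))
  truth <- sim$cohort$truth
  jsonlite::write_json(
    list(icrs = truth$icrs, imprinted_genes = truth$imprinted_genes,
         pedigree = truth$pedigree),
    file.path(dir, "truth.json"), dataframe = "rows", na = "null")
  invisible(dir)
}

# minimal phased VCF v4.2 writer (GT only)
write_phased_vcf <- function(genotypes, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=imprintscan-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  body <- cbind(genotypes$chrom, genotypes$pos, ".", genotypes$ref,
                genotypes$alt, ".", "PASS", ".", "GT",
                as.matrix(genotypes[, samples, drop = FALSE]))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read heterozygous variants of one sample from a VCF
#'
#' @param path VCF file.
#' @param sample Sample name (defaults to the first sample).
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `gt` restricted to
#'   heterozygous single-nucleotide sites.
#' @export
read_het_variants <- function(path, sample = NULL) {
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_all <- vcfR::extract.gt(v, element = "GT")
  sample <- sample %||% colnames(gt_all)[1]
  gt <- gt_all[, sample]
  fix <- tibble::tibble(chrom = vcfR::getCHROM(v),
                        pos = vcfR::getPOS(v),
                        ref = vcfR::getREF(v),
                        alt = vcfR::getALT(v),
                        gt = unname(gt))
  fix[fix$gt %in% c("0|1", "1|0", "0/1", "1/0") &
        nchar(fix$ref) == 1 & nchar(fix$alt) == 1, ]
}

#' Read a simulator reads TSV back into per-read tables
#'
#' Inverse of the `reads.tsv` written by [write_simulation()]. An optional
#' logical `pass` column, when present, drops failed reads on input.
#'
#' @param path `reads.tsv` path.
#' @return A list with `reads`, `read_snps`, `read_cpgs` tibbles.
#' @export
read_reads_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if ("pass" %in% names(d)) d <- d[is.na(d$pass) | d$pass, ]
  parse_list <- function(read_id, chrom, s, value_name) {
    keep <- !is.na(s) & s != ""
    parts <- strsplit(s[keep], ",", fixed = TRUE)
    n <- lengths(parts)
    flat <- unlist(parts)
    kv <- strsplit(flat, ":", fixed = TRUE)
    out <- tibble::tibble(
      read_id = rep(read_id[keep], n),
      chrom = rep(chrom[keep], n),
      pos = as.integer(vapply(kv, `[`, "", 1L)))
    out[[value_name]] <- as.integer(vapply(kv, `[`, "", 2L))
    out
  }
  list(
    reads = d[, c("read_id", "individual", "chrom", "start", "end")],
    read_snps = parse_list(d$read_id, d$chrom, d$snps, "allele"),
    read_cpgs = parse_list(d$read_id, d$chrom, d$cpgs, "methylated"))
}

#' Write ASM sites as BED6+
#'
#' Columns: chrom, start, end, name (annotated gene or "."), score
#' (differential CpG count), strand ".", then mean per-haplotype
#' methylation.
#'
#' @param sites Output of [annotate_asm_sites()] (or [call_asm_sites()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_asm_bed <- function(sites, path) {
  bed <- tibble::tibble(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = if ("gene_id" %in% names(sites))
      ifelse(is.na(sites$gene_id), ".", sites$gene_id) else ".",
    score = sites$n_cpg, strand = ".",
    mean_hap1 = round(sites$mean_hap1, 4),
    mean_hap2 = round(sites$mean_hap2, 4))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write per-haplotype methylation counts as a bedMethyl-like TSV
#'
#' One row per CpG per haplotype: chrom, 0-based start, end, haplotype,
#' methylated count, total count.
#'
#' @param counts Output of [haplotype_methylation_counts()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hap_methylation <- function(counts, path) {
  long <- dplyr::bind_rows(
    tibble::tibble(chrom = counts$chrom, start = counts$pos - 1L,
                   end = counts$pos, hap = "hap1",
                   meth = counts$hap1_meth, total = counts$hap1_total),
    tibble::tibble(chrom = counts$chrom, start = counts$pos - 1L,
                   end = counts$pos, hap = "hap2",
                   meth = counts$hap2_meth, total = counts$hap2_total))
  readr::write_tsv(dplyr::arrange(long, .data$chrom, .data$start,
                                  .data$hap),
                   path, col_names = FALSE)
  invisible(path)
}
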