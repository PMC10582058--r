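# End-to-end imprinted-gene scan on a simulated (or assembled) dataset:
# phasing -> ASM -> monoallelic expression -> ASM linkage -> gene screen ->
# duo parent-of-origin -> germline ICR concordance.

#' Scan a dataset for imprinted genes
#'
#' Chains the full discovery pipeline on an `imprint_sim` object (or any
#' list with the same components): phases the focal individual's long
#' reads, tallies per-haplotype CpG methylation, calls and annotates ASM
#' sites, screens allelic RNA counts for monoallelic expression at the
#' sample's DNA-heterozygous sites (Bonferroni per sample x tissue),
#' links significant SNPs to ASM sites within `link_distance`, screens
#' gene candidates with the biallelic-exclusion rule, classifies parent of
#' origin from mother-offspring duos, and screens ASM sites for germline
#' ICR behaviour when germline libraries are present.
#'
#' @param sim An [simulate_cohort()] result.
#' @param min_cpg,max_gap,alpha_cpg,min_depth_per_hap ASM parameters, see
#'   [call_asm_sites()] and [test_cpg_differential()].
#' @param annotation_window Gene annotation window, bp
#'   (see [annotate_asm_sites()]).
#' @param min_depth,alpha Monoallelic screen parameters
#'   (see [call_monoallelic()]).
#' @param link_distance SNP-to-ASM linkage cut-off, bp (default 1e6).
#' @param biallelic_minor_fraction Gene-screen exclusion threshold.
#' @param detection_fraction Expressed-allele detection fraction.
#' @param min_duos Minimum agreeing duos for a parent-of-origin call.
#' @return An `imprint_scan` object: `blocks`, `methylation_counts`,
#'   `asm_sites`, `monoallelic_calls`, `linked_calls`, `gene_screen`,
#'   `candidates`, `expressed_genotypes`, `duo_assignments`,
#'   `imprint_calls`, `icr_screen`.
#' @export
scan_imprinting <- function(sim,
                            min_cpg = 20L, max_gap = 5000L,
                            alpha_cpg = 0.01, min_depth_per_hap = 5L,
                            annotation_window = 20000L,
                            min_depth = 10L, alpha = 0.05,
                            link_distance = 1e6,
                            biallelic_minor_fraction = 0.2,
                            detection_fraction = 0.2,
                            min_duos = 2L) {
  focal <- sim$focal_individuals[1]
  gt <- sim$cohort$genotypes
  samples <- sim$cohort$samples
  gt_mat <- as.matrix(gt[, samples, drop = FALSE])
  het_codes <- c("0|1", "1|0")

  # --- phasing + ASM on the focal individual ---
  het <- gt[gt_mat[, focal] %in% het_codes, c("chrom", "pos", "ref", "alt")]
  focal_reads <- sim$reads$reads$read_id[sim$reads$reads$individual == focal]
  rs <- sim$reads$read_snps[sim$reads$read_snps$read_id %in% focal_reads, ]
  rc <- sim$reads$read_cpgs[sim$reads$read_cpgs$read_id %in% focal_reads, ]
  blocks <- suppressMessages(phase_variants(rs, het))
  assignments <- assign_read_haplotypes(rs, blocks, read_ids = focal_reads)
  hmc <- haplotype_methylation_counts(rc, assignments)
  diff_cpgs <- test_cpg_differential(hmc, min_depth_per_hap = min_depth_per_hap,
                                     alpha = alpha_cpg)
  asm_sites <- call_asm_sites(diff_cpgs, min_cpg = min_cpg,
                              max_gap = max_gap) |>
    annotate_asm_sites(sim$panel$genes, window = annotation_window)

  # --- monoallelic expression at each sample's DNA-het sites ---
  counts <- sim$rna$allelic_counts
  gt_row <- match(paste(counts$chrom, counts$pos),
                  paste(gt$chrom, gt$pos))
  gt_col <- match(counts$sample, samples)
  counts$dna_genotype <- gt_mat[cbind(gt_row, gt_col)]
  het_counts <- counts[counts$dna_genotype %in% het_codes, ]
  calls <- call_monoallelic(het_counts, min_depth = min_depth,
                            alpha = alpha)
  linked <- link_candidates_to_asm(calls, asm_sites,
                                   max_distance = link_distance)
  gene_screen <- screen_gene_candidates(
    linked, calls, biallelic_minor_fraction = biallelic_minor_fraction,
    min_depth = min_depth)
  candidates <- gene_screen[!gene_screen$excluded, ]

  # --- expressed genotypes + duo parent-of-origin for candidate genes ---
  cand_counts <- counts[counts$gene_id %in% candidates$gene_id, ]
  expressed <- collect_expressed_genotypes(
    cand_counts, detection_fraction = detection_fraction)
  if (nrow(expressed) > 0) {
    dna_het_tbl <- cand_counts |>
      dplyr::distinct(.data$sample, .data$gene_id, .data$dna_genotype) |>
      dplyr::group_by(.data$sample, .data$gene_id) |>
      dplyr::summarise(dna_het = any(.data$dna_genotype %in% het_codes),
                       .groups = "drop")
    expressed <- dplyr::left_join(expressed, dna_het_tbl,
                                  by = c("sample", "gene_id"))
  }
  duo_assignments <- build_duo_assignments(
    cand_counts, sim$cohort$truth$pedigree, het_codes, min_depth = 5L)
  imprint_calls <- classify_imprint(duo_assignments, expressed,
                                    min_duos = min_duos)

  # --- germline ICR screen over the called ASM sites ---
  icr_screen <- NULL
  if (!is.null(sim$germline) && nrow(asm_sites) > 0 &&
      nrow(sim$germline$region_calls) > 0) {
    rm_tbl <- region_methylation(sim$germline$region_calls, asm_sites)
    by_type <- rm_tbl |>
      dplyr::left_join(
        sim$germline$libraries[, c("library_id", "cell_type")],
        by = "library_id") |>
      dplyr::group_by(.data$site_id, .data$cell_type) |>
      dplyr::summarise(
        percent = if (all(is.na(.data$total))) NA_real_ else
          100 * sum(.data$methylated, na.rm = TRUE) /
            sum(.data$total, na.rm = TRUE),
        .groups = "drop") |>
      tidyr::pivot_wider(names_from = "cell_type",
                         values_from = "percent")
    for (col in c("soma", "PGC", "sperm"))
      if (!col %in% names(by_type)) by_type[[col]] <- NA_real_
    site_meth <- by_type |>
      dplyr::transmute(site_id = .data$site_id,
                       soma_percent = .data$soma,
                       pgc_percent = .data$PGC,
                       sperm_percent = .data$sperm) |>
      dplyr::left_join(asm_sites[, c("site_id", "gene_id")], by = "site_id")
    icr_screen <- screen_icr_candidates(site_meth)
  }

  structure(list(
    focal = focal, blocks = blocks, methylation_counts = hmc,
    diff_cpgs = diff_cpgs, asm_sites = asm_sites,
    monoallelic_calls = calls, linked_calls = linked,
    gene_screen = gene_screen, candidates = candidates,
    expressed_genotypes = expressed, duo_assignments = duo_assignments,
    imprint_calls = imprint_calls, icr_screen = icr_screen
  ), class = "imprint_scan")
}

# One row per (offspring duo, gene): parent of origin of the expressed
# allele, collapsed over the duo's informative SNPs (internally discordant
# duos are demoted to uninformative).
build_duo_assignments <- function(cand_counts, pedigree, het_codes,
                                  min_depth = 5L) {
  empty <- tibble::tibble(gene_id = character(), offspring = character(),
                          mother = character(), origin = character())
  duos <- pedigree[!is.na(pedigree$mother), ]
  if (nrow(duos) == 0L || nrow(cand_counts) == 0L) return(empty)
  off_counts <- cand_counts[cand_counts$sample %in% duos$sample, ]
  if (nrow(off_counts) == 0L) return(empty)
  per_snp <- off_counts |>
    dplyr::group_by(.data$sample, .data$gene_id, .data$chrom, .data$pos) |>
    dplyr::summarise(ref_count = sum(.data$ref_count),
                     alt_count = sum(.data$alt_count),
                     offspring_genotype = gt_class(.data$dna_genotype[1]),
                     .groups = "drop") |>
    dplyr::mutate(depth = .data$ref_count + .data$alt_count) |>
    dplyr::filter(.data$depth >= min_depth,
                  .data$ref_count != .data$alt_count) |>
    dplyr::mutate(offspring_expressed = ifelse(
      .data$ref_count > .data$alt_count, "ref", "alt")) |>
    dplyr::left_join(duos, by = "sample")
  # mother DNA genotype at the same SNPs
  mom_gt <- cand_counts |>
    dplyr::distinct(.data$sample, .data$chrom, .data$pos,
                    .data$dna_genotype) |>
    dplyr::rename(mother = "sample",
                  mother_genotype_code = "dna_genotype")
  per_snp <- per_snp |>
    dplyr::inner_join(mom_gt, by = c("mother", "chrom", "pos")) |>
    dplyr::mutate(mother_genotype = gt_class(.data$mother_genotype_code))
  if (nrow(per_snp) == 0L) return(empty)
  assigned <- assign_duo_origin(per_snp)
  assigned |>
    dplyr::group_by(.data$gene_id, offspring = .data$sample,
                    .data$mother) |>
    dplyr::summarise(origin = {
      inf <- unique(.data$origin[.data$origin %in%
                                   c("maternal", "paternal")])
      if (any(.data$origin == "inconsistent")) "inconsistent"
      else if (length(inf) == 1L) inf
      else "uninformative"
    }, .groups = "drop")
}

# phased VCF-style GT string -> genotype class
gt_class <- function(gt) {
  dplyr::case_when(
    gt %in% c("0|0", "0/0") ~ "hom_ref",
    gt %in% c("1|1", "1/1") ~ "hom_alt",
    gt %in% c("0|1", "1|0", "0/1", "1/0") ~ "het",
    TRUE ~ NA_character_)
}

#' @export
print.imprint_scan <- function(x, ...) {
  cat("<imprint_scan>\n")
  cat(sprintf("  focal individual: %s; %d phase blocks; %d ASM sites\n",
              x$focal, length(unique(x$blocks$block_id)),
              nrow(x$asm_sites)))
  cat(sprintf("  %d candidate genes; imprint calls: %s\n",
              nrow(x$candidates),
              paste(sprintf("%s=%d", names(table(x$imprint_calls$status)),
                            table(x$imprint_calls$status)),
                    collapse = ", ")))
  invisible(x)
}
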