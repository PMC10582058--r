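# Population-level imprinting evidence: expressed genotypes, exact
# Hardy-Weinberg heterozygote-deficiency test, duo-based parent-of-origin
# and the final imprint classification.

#' Collect expressed genotypes from allelic counts
#'
#' Per sample, gene and SNP (pooling tissues), the set of alleles expressed
#' at detectable fraction: an allele counts as expressed when its fraction
#' is at least `detection_fraction` at pooled depth at least `min_depth`.
#' Gene level aggregates across SNPs: a sample is expressed-heterozygous for
#' a gene iff any SNP shows both alleles; `discordant` flags genes whose
#' SNPs disagree on the number of expressed alleles.
#'
#' @param counts Allelic counts (`sample`, `gene_id`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`; tissue rows are pooled).
#' @param detection_fraction Minimum allele fraction to call an allele
#'   expressed (default 0.2).
#' @param min_depth Minimum pooled depth per SNP (default 5; shallower SNPs
#'   are dropped).
#' @return Tibble per sample x gene: `n_snps`, `expressed_het`,
#'   `expressed_alleles` (of the first informative SNP), `discordant`.
#' @export
collect_expressed_genotypes <- function(counts, detection_fraction = 0.2,
                                        min_depth = 5L) {
  per_snp <- counts |>
    dplyr::group_by(.data$sample, .data$gene_id, .data$chrom, .data$pos) |>
    dplyr::summarise(ref_count = sum(.data$ref_count),
                     alt_count = sum(.data$alt_count), .groups = "drop") |>
    dplyr::mutate(depth = .data$ref_count + .data$alt_count) |>
    dplyr::filter(.data$depth >= min_depth) |>
    dplyr::mutate(
      ref_expr = .data$ref_count / .data$depth >= detection_fraction,
      alt_expr = .data$alt_count / .data$depth >= detection_fraction,
      n_expr = as.integer(.data$ref_expr) + as.integer(.data$alt_expr),
      alleles = dplyr::case_when(
        .data$ref_expr & .data$alt_expr ~ "ref,alt",
        .data$ref_expr ~ "ref",
        .data$alt_expr ~ "alt",
        TRUE ~ NA_character_))
  per_snp |>
    dplyr::filter(!is.na(.data$alleles)) |>
    dplyr::group_by(.data$sample, .data$gene_id) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      expressed_het = any(.data$n_expr == 2L),
      expressed_alleles = .data$alleles[1],
      discordant = dplyr::n_distinct(.data$n_expr) > 1L,
      .groups = "drop")
}

#' Exact one-sided Hardy-Weinberg test for heterozygote deficiency
#'
#' Conditional on the observed allele counts, the probability of observing
#' at most the observed number of heterozygotes under random union of
#' gametes:
#' `P(n_AB) = N! / (n_AA! n_AB! n_BB!) * 2^n_AB * n_A! n_B! / (2N)!`,
#' summed over all configurations with no more heterozygotes than observed.
#' A genome-wide deficiency of expressed heterozygotes is the population
#' signature of imprinting (every individual appears to express one allele).
#'
#' @param n_AA,n_AB,n_BB Genotype counts.
#' @return One-sided p-value (small when heterozygotes are deficient).
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  stopifnot(length(n_AA) == 1L, length(n_AB) == 1L, length(n_BB) == 1L)
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("genotype counts must be >= 0")
  N <- n_AA + n_AB + n_BB
  if (N < 1) stop("undefined: no genotyped individuals")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  ks <- seq(nA %% 2, min(nA, nB), by = 2)
  ks <- ks[ks <= n_AB]
  if (length(ks) == 0L) return(0)
  logp <- lfactorial(N) - lfactorial((nA - ks) / 2) - lfactorial(ks) -
    lfactorial((nB - ks) / 2) + ks * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * N)
  min(1, sum(exp(logp)))
}

#' Assign parent of origin of the expressed allele in mother-offspring duos
#'
#' Informative iff the mother is homozygous and the offspring heterozygous:
#' the allele the mother cannot have transmitted is paternal. Genotypes
#' sharing no allele between mother and offspring are flagged
#' `inconsistent` (a pedigree error signal); everything else is
#' `uninformative`. Symmetric under ref/alt relabelling.
#'
#' @param duos Tibble with `mother_genotype`, `offspring_genotype`
#'   (`hom_ref`/`het`/`hom_alt`) and `offspring_expressed` (`ref`/`alt`).
#'   Other columns (sample, gene, SNP ids) are carried through.
#' @return `duos` with an `origin` column in `maternal`, `paternal`,
#'   `uninformative`, `inconsistent`.
#' @export
assign_duo_origin <- function(duos) {
  mg <- duos$mother_genotype
  og <- duos$offspring_genotype
  ex <- duos$offspring_expressed
  origin <- dplyr::case_when(
    (mg == "hom_ref" & og == "hom_alt") |
      (mg == "hom_alt" & og == "hom_ref") ~ "inconsistent",
    mg == "het" | og != "het" ~ "uninformative",
    mg == "hom_ref" & ex == "alt" ~ "paternal",
    mg == "hom_ref" & ex == "ref" ~ "maternal",
    mg == "hom_alt" & ex == "ref" ~ "paternal",
    mg == "hom_alt" & ex == "alt" ~ "maternal",
    TRUE ~ "uninformative")
  dplyr::mutate(duos, origin = origin)
}

#' Classify the imprinting status of genes from duo evidence
#'
#' A gene is called `maternal_expressed` or `paternal_expressed` iff at
#' least `min_duos` informative duos agree unanimously on the origin of the
#' expressed allele; any disagreement gives `conflicting`; fewer informative
#' duos give `insufficient` (with `provisional` set when a single duo
#' points one way). Heterozygote-deficiency evidence (exact HWE p on
#' expressed genotypes) and the count of DNA-heterozygous,
#' expression-monoallelic individuals are attached as supporting evidence,
#' never as a gate.
#'
#' @param duo_assignments Output of [assign_duo_origin()], one row per duo
#'   per gene (multi-SNP duos already collapsed), with `gene_id`.
#' @param expressed_genotypes Optional output of
#'   [collect_expressed_genotypes()]; may carry a logical `dna_het` column.
#' @param min_duos Minimum agreeing informative duos (default 2).
#' @return Tibble per gene: `status`, `n_informative_duos`, `n_maternal`,
#'   `n_paternal`, `provisional`, `n_monoallelic_het`, `hwe_p`.
#' @export
classify_imprint <- function(duo_assignments, expressed_genotypes = NULL,
                             min_duos = 2L) {
  base <- duo_assignments |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_maternal = sum(.data$origin == "maternal"),
      n_paternal = sum(.data$origin == "paternal"),
      .groups = "drop") |>
    dplyr::mutate(
      n_informative_duos = .data$n_maternal + .data$n_paternal,
      status = dplyr::case_when(
        .data$n_maternal > 0 & .data$n_paternal > 0 ~ "conflicting",
        .data$n_maternal >= min_duos ~ "maternal_expressed",
        .data$n_paternal >= min_duos ~ "paternal_expressed",
        TRUE ~ "insufficient"),
      provisional = .data$status == "insufficient" &
        .data$n_informative_duos == 1L)
  if (!is.null(expressed_genotypes)) {
    ev <- expressed_genotypes |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        n_monoallelic_het = if ("dna_het" %in% names(expressed_genotypes))
          sum(.data$dna_het & !.data$expressed_het, na.rm = TRUE)
        else NA_integer_,
        hwe_p = {
          n_het <- sum(.data$expressed_het)
          n_hom_ref <- sum(!.data$expressed_het &
                             .data$expressed_alleles == "ref")
          n_hom_alt <- sum(!.data$expressed_het &
                             .data$expressed_alleles == "alt")
          if (n_het + n_hom_ref + n_hom_alt >= 1)
            hwe_exact_test(n_hom_ref, n_het, n_hom_alt) else NA_real_
        },
        .groups = "drop")
    base <- dplyr::left_join(base, ev, by = "gene_id")
  } else {
    base$n_monoallelic_het <- NA_integer_
    base$hwe_p <- NA_real_
  }
  dplyr::select(base, "gene_id", "status", "n_informative_duos",
                "n_maternal", "n_paternal", "provisional",
                "n_monoallelic_het", "hwe_p") |>
    dplyr::arrange(.data$gene_id)
}
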