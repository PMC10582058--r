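#' Configuration for the synthetic imprinting cohort
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe an admixed, highly heterozygous diploid cohort of 40 individuals
#' (half with their mother also sampled), a 3 Mb two-chromosome genome with
#' 500 genes, and 10 imprint control regions (ICRs) each driving
#' parent-specific expression of its neighbouring gene. Long reads are drawn
#' at 30-fold coverage with 1% per-CpG methylation-call error, and allelic
#' RNA counts at Poisson(30) depth across three tissues.
#'
#' @param seed Master integer seed; every output stream is sub-seeded from it.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param cpg_density Background CpGs per kb (ICR islands are denser).
#' @param snp_density Panel SNPs per kb. With allele frequencies drawn
#'   uniform on (0.2, 0.8) the per-individual heterozygous density is about
#'   0.49 times this value; the default of 7/kb reproduces the ~0.35%
#'   per-individual heterozygosity of a highly admixed reference animal.
#' @param n_individuals Cohort size.
#' @param fraction_with_mother Proportion of individuals whose mother is also
#'   in the cohort (mother-offspring duos).
#' @param n_genes Number of gene models.
#' @param n_icrs Number of ICRs; each is the promoter CpG island of one
#'   imprinted gene.
#' @param icr_cpg_count CpGs per promoter/ICR island. The default of 60 in
#'   a 1.2 kb island (5 CpGs per 100 bp) matches the dinucleotide density
#'   that defines CpG islands; keep >= 25 so the 20-CpG site filter remains
#'   discoverable.
#' @param fraction_maternal_methylated_icrs Proportion of ICRs methylated on
#'   the maternal allele (hence paternally expressed genes).
#' @param icr_gene_max_distance Maximum ICR-to-gene distance in bp for truth
#'   genes; must be <= 1e6 so truth genes are discoverable under the 1 Mb
#'   linkage rule.
#' @param leaky_fraction Proportion of imprinted genes with leaky
#'   (biased rather than absolute) monoallelic expression.
#' @param leaky_minor_fraction Expression fraction of the silenced allele in
#'   leaky genes (default 0.15, below the 0.2 amplicon detection threshold).
#' @param gene_length Gene model length in bp.
#' @param read_length Long-read length in bp.
#' @param read_depth Long-read fold coverage for focal individuals.
#' @param methylation_call_error Probability a per-read CpG state is flipped.
#' @param snp_read_error Probability a read reports the wrong SNP allele.
#' @param rna_depth_mean Expected RNA reads per expressed SNP per tissue.
#' @param n_tissues Number of tissues with allelic RNA counts.
#' @param background_methylation Genome-wide CpG methylation level outside
#'   ICRs (both haplotypes).
#' @param icr_methylated_level,icr_unmethylated_level Per-CpG methylation
#'   probability of the methylated / unmethylated parental allele at ICRs.
#'   Defaults 1 and 0: the parental states are deterministic and all
#'   observation noise flows through `methylation_call_error`.
#' @param pgc_icr_level ICR methylation in demethylated-stage primordial germ
#'   cells (erasure residue; the study reports 5-21%).
#' @param noncg_level Residual non-CpG methylation (bisulfite non-conversion).
#' @param germline_stage_means Named vector of global CpG methylation
#'   fractions per germline stage: `pre`, `demethylated`, `remethylated`,
#'   `sperm`, `soma`. Defaults follow the high-low-high reprogramming
#'   trajectory (0.697 at birth, 0.411 demethylated, 0.65 remethylated).
#' @param exonic_snps_per_gene Minimum exonic SNPs guaranteed per gene, so
#'   expressed genes are testable for allelic imbalance.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1.5e6,
                       cpg_density = 8,
                       snp_density = 7,
                       n_individuals = 40L,
                       fraction_with_mother = 0.5,
                       n_genes = 500L,
                       n_icrs = 10L,
                       icr_cpg_count = 60L,
                       fraction_maternal_methylated_icrs = 0.7,
                       icr_gene_max_distance = 5e5,
                       leaky_fraction = 0.2,
                       leaky_minor_fraction = 0.15,
                       gene_length = 1500L,
                       read_length = 8000L,
                       read_depth = 30,
                       methylation_call_error = 0.01,
                       snp_read_error = 0.01,
                       rna_depth_mean = 30,
                       n_tissues = 3L,
                       background_methylation = 0.70,
                       icr_methylated_level = 1,
                       icr_unmethylated_level = 0,
                       pgc_icr_level = 0.12,
                       noncg_level = 0.01,
                       germline_stage_means = c(pre = 0.697,
                                                demethylated = 0.411,
                                                remethylated = 0.65,
                                                sperm = 0.65,
                                                soma = 0.70),
                       exonic_snps_per_gene = 2L) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, cpg_density = cpg_density,
    snp_density = snp_density, n_individuals = as.integer(n_individuals),
    fraction_with_mother = fraction_with_mother,
    n_genes = as.integer(n_genes), n_icrs = as.integer(n_icrs),
    icr_cpg_count = as.integer(icr_cpg_count),
    fraction_maternal_methylated_icrs = fraction_maternal_methylated_icrs,
    icr_gene_max_distance = icr_gene_max_distance,
    leaky_fraction = leaky_fraction,
    leaky_minor_fraction = leaky_minor_fraction,
    gene_length = as.integer(gene_length),
    read_length = as.integer(read_length), read_depth = read_depth,
    methylation_call_error = methylation_call_error,
    snp_read_error = snp_read_error, rna_depth_mean = rna_depth_mean,
    n_tissues = as.integer(n_tissues),
    background_methylation = background_methylation,
    icr_methylated_level = icr_methylated_level,
    icr_unmethylated_level = icr_unmethylated_level,
    pgc_icr_level = pgc_icr_level, noncg_level = noncg_level,
    germline_stage_means = germline_stage_means,
    exonic_snps_per_gene = as.integer(exonic_snps_per_gene)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("fraction_with_mother", "fraction_maternal_methylated_icrs",
             "leaky_fraction", "leaky_minor_fraction",
             "methylation_call_error", "snp_read_error",
             "background_methylation", "icr_methylated_level",
             "icr_unmethylated_level", "pgc_icr_level", "noncg_level")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a proportion in [0, 1], got %s", p, v))
  }
  counts <- c("n_chromosomes", "chrom_length", "n_individuals",
              "icr_cpg_count", "gene_length", "read_length")
  for (p in counts) {
    if (cfg[[p]] <= 0) stop(sprintf("`%s` must be positive", p))
  }
  if (cfg$n_genes < 0 || cfg$n_icrs < 0)
    stop("`n_genes` and `n_icrs` must be non-negative")
  if (cfg$n_icrs > cfg$n_genes)
    stop("`n_icrs` cannot exceed `n_genes`")
  if (cfg$icr_gene_max_distance > 1e6)
    stop("`icr_gene_max_distance` must be <= 1,000,000 bp so truth genes ",
         "remain discoverable under the 1 Mb ASM linkage rule")
  if (cfg$fraction_with_mother > 0 && cfg$n_individuals < 2)
    stop("pedigree error: `fraction_with_mother` > 0 requires at least two ",
         "individuals")
  if (any(cfg$germline_stage_means < 0 | cfg$germline_stage_means > 1))
    stop("config error: germline stage means must lie in [0, 1]")
  needed <- c("pre", "demethylated", "remethylated", "sperm", "soma")
  if (!all(needed %in% names(cfg$germline_stage_means)))
    stop("`germline_stage_means` must name: ",
         paste(needed, collapse = ", "))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp, %d genes, %d ICRs\n",
              x$n_chromosomes, format(x$chrom_length, big.mark = ","),
              x$n_genes, x$n_icrs))
  cat(sprintf("  cohort: %d individuals (%.0f%% with mother), seed %d\n",
              x$n_individuals, 100 * x$fraction_with_mother, x$seed))
  cat(sprintf("  reads: %dx @ %d bp, CpG call error %.3f, SNP error %.3f\n",
              round(x$read_depth), x$read_length, x$methylation_call_error,
              x$snp_read_error))
  invisible(x)
}
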