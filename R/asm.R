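# Allele-specific methylation: per-CpG exact tests between haplotypes,
# clustering into ASM sites, and gene annotation.

#' Test each CpG for differential methylation between haplotypes
#'
#' Two-sided conditional exact test (2x2: methylated/unmethylated by
#' haplotype) per CpG. CpGs with fewer than `min_depth_per_hap` assigned
#' reads on either haplotype are skipped. No multiple-testing correction is
#' applied at this stage: the downstream cluster-size filter
#' ([call_asm_sites()]) is the false-positive control.
#'
#' @param counts Output of [haplotype_methylation_counts()].
#' @param min_depth_per_hap Minimum assigned reads per haplotype (default 5).
#' @param alpha Per-CpG significance level (default 0.01).
#' @return Tibble: `chrom`, `pos`, `hap1_frac`, `hap2_frac`, `p`,
#'   `direction` (sign of hap1 - hap2), `differential`.
#' @export
test_cpg_differential <- function(counts, min_depth_per_hap = 5L,
                                  alpha = 0.01) {
  keep <- counts$hap1_total >= min_depth_per_hap &
    counts$hap2_total >= min_depth_per_hap
  d <- counts[keep, ]
  if (nrow(d) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          hap1_frac = numeric(), hap2_frac = numeric(),
                          p = numeric(), direction = integer(),
                          differential = logical()))
  }
  p <- fisher2x2_p(d$hap1_meth, d$hap1_total, d$hap2_meth, d$hap2_total)
  f1 <- d$hap1_meth / d$hap1_total
  f2 <- d$hap2_meth / d$hap2_total
  tibble::tibble(chrom = d$chrom, pos = d$pos,
                 hap1_frac = f1, hap2_frac = f2, p = p,
                 direction = as.integer(sign(f1 - f2)),
                 differential = p < alpha)
}

#' Cluster differential CpGs into allele-specific methylation sites
#'
#' Differential CpGs are clustered by single linkage with inter-CpG gap
#' `<= max_gap`; a cluster is reported as an ASM site iff it contains at
#' least `min_cpg` differential CpGs and at least
#' `min_direction_consistency` of them share one direction.
#'
#' @param diff_cpgs Output of [test_cpg_differential()] (rows with
#'   `differential == FALSE` are ignored).
#' @param min_cpg Minimum differential CpGs per site (default 20).
#' @param max_gap Maximum intra-site gap between consecutive differential
#'   CpGs, bp (default 5000).
#' @param min_direction_consistency Minimum fraction of member CpGs sharing
#'   the majority direction (default 0.9).
#' @return Tibble of sites (0-based half-open intervals): `site_id`,
#'   `chrom`, `start`, `end`, `n_cpg`, `mean_hap1`, `mean_hap2`,
#'   `direction` (majority).
#' @export
call_asm_sites <- function(diff_cpgs, min_cpg = 20L, max_gap = 5000L,
                           min_direction_consistency = 0.9) {
  stopifnot("differential" %in% names(diff_cpgs))
  d <- diff_cpgs[diff_cpgs$differential, ]
  empty <- tibble::tibble(site_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_cpg = integer(), mean_hap1 = numeric(),
                          mean_hap2 = numeric(), direction = integer())
  if (nrow(d) == 0L) return(empty)
  d <- dplyr::arrange(d, .data$chrom, .data$pos)
  newc <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
              d$pos[-1] - d$pos[-nrow(d)] > max_gap)
  d$cluster <- cumsum(newc)
  sites <- d |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos) - 1L,
      end = max(.data$pos),
      n_cpg = dplyr::n(),
      mean_hap1 = mean(.data$hap1_frac),
      mean_hap2 = mean(.data$hap2_frac),
      consistency = max(sum(.data$direction > 0),
                        sum(.data$direction < 0)) / dplyr::n(),
      direction = as.integer(sign(sum(sign(.data$direction)))),
      .groups = "drop") |>
    dplyr::filter(.data$n_cpg >= min_cpg,
                  .data$consistency >= min_direction_consistency) |>
    dplyr::select(-"cluster", -"consistency")
  if (nrow(sites) == 0L) return(empty)
  sites |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(site_id = sprintf("asm%03d", dplyr::row_number()),
                  .before = 1)
}

#' Annotate ASM sites with the nearest gene
#'
#' Each site is annotated with the gene whose span lies nearest to the site
#' midpoint, provided that distance is at most `window` (0 when the midpoint
#' falls inside the gene). Equidistant genes are broken towards the
#' lexicographically smaller gene id, so annotation is reproducible.
#'
#' @param sites Output of [call_asm_sites()].
#' @param genes Gene models: `gene_id`, `chrom`, `start`, `end`.
#' @param window Maximum midpoint-to-gene distance in bp (default 20000).
#' @return `sites` with `gene_id` (NA when no gene qualifies) and
#'   `gene_distance` columns added.
#' @export
annotate_asm_sites <- function(sites, genes, window = 20000L) {
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  gene_distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == sites$chrom[i], ]
    if (nrow(g) == 0L) next
    mid <- (sites$start[i] + sites$end[i]) / 2
    dist <- pmax(0, g$start - mid, mid - g$end)
    ok <- which(dist <= window)
    if (length(ok) == 0L) next
    best <- min(dist[ok])
    cand <- g$gene_id[ok][dist[ok] == best]
    gene_id[i] <- sort(cand)[1]
    gene_distance[i] <- best
  }
  dplyr::mutate(sites, gene_id = gene_id, gene_distance = gene_distance)
}
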