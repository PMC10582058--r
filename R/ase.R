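# Allele-specific expression: per-SNP monoallelic tests against expected
# 1:1 counts, Bonferroni correction, ASM linkage and the gene-level screen.

#' Test per-SNP allelic counts for monoallelic expression
#'
#' For each row, a two-sided Fisher exact test compares the observed
#' (ref, alt) counts against the expected counts under biallelic 1:1
#' expression, `(ceiling(depth/2), floor(depth/2))`. Rows below `min_depth`
#' are reported as underpowered with no p-value. A binomial exact test
#' against 0.5 is available for sensitivity analysis.
#'
#' @param counts Tibble with `ref_count` and `alt_count` columns (any
#'   identifier columns are carried through).
#' @param min_depth Minimum total depth to test (default 10).
#' @param method `"fisher"` (observed-vs-expected table, default) or
#'   `"binomial"` (exact binomial against 0.5).
#' @return `counts` with `depth`, `p`, `expressed_allele` (majority; `ref`
#'   on an exact tie), `minor_fraction`, and `verdict` (`"underpowered"` or
#'   NA, finalised by [call_monoallelic()]).
#' @export
monoallelic_test <- function(counts, min_depth = 10L,
                             method = c("fisher", "binomial")) {
  method <- match.arg(method)
  if (any(counts$ref_count < 0 | counts$alt_count < 0))
    stop("input error: negative allelic counts")
  depth <- counts$ref_count + counts$alt_count
  p <- rep(NA_real_, length(depth))
  ok <- depth >= min_depth
  if (any(ok)) {
    if (method == "fisher") {
      p[ok] <- fisher2x2_p(counts$ref_count[ok], depth[ok],
                           ceiling(depth[ok] / 2), depth[ok])
    } else {
      p[ok] <- vapply(which(ok), function(i)
        stats::binom.test(counts$ref_count[i], depth[i], 0.5)$p.value,
        numeric(1))
    }
  }
  dplyr::mutate(
    counts,
    depth = depth,
    p = p,
    expressed_allele = ifelse(.data$ref_count >= .data$alt_count,
                              "ref", "alt"),
    minor_fraction = ifelse(depth > 0,
                            pmin(.data$ref_count, .data$alt_count) / depth,
                            NA_real_),
    verdict = ifelse(depth < min_depth, "underpowered", NA_character_))
}

#' Bonferroni-adjust a vector of p-values
#'
#' `adjusted = min(1, m * p)` with `m` defaulting to the number of
#' non-missing p-values (the tested SNPs of one screen). Missing values
#' (underpowered tests) stay missing and do not count towards `m`.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size override.
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni_adjust <- function(p, m = NULL) {
  if (length(p) == 0L) return(numeric())
  m <- m %||% sum(!is.na(p))
  pmin(1, m * p)
}

#' Run the monoallelic-expression screen with Bonferroni control
#'
#' Applies [monoallelic_test()] and Bonferroni correction with the family
#' defined per screen group (default: each sample and tissue is its own
#' screen, the study design where one individual's tissues are screened
#' separately). Verdicts: `monoallelic` if adjusted p < `alpha`,
#' `biallelic` otherwise, `underpowered` below `min_depth`.
#'
#' @inheritParams monoallelic_test
#' @param by Character vector of grouping columns defining one screen
#'   family (default `c("sample", "tissue")`; use `"tissue"` to pool
#'   samples per tissue).
#' @param alpha Family-wise significance level (default 0.05).
#' @return `counts` with test columns, `p_adjusted` and final `verdict`.
#' @export
call_monoallelic <- function(counts, min_depth = 10L, alpha = 0.05,
                             by = c("sample", "tissue"),
                             method = c("fisher", "binomial")) {
  res <- monoallelic_test(counts, min_depth = min_depth, method = method)
  by <- intersect(by, names(res))
  res <- res |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(p_adjusted = bonferroni_adjust(.data$p)) |>
    dplyr::ungroup()
  dplyr::mutate(res, verdict = dplyr::case_when(
    !is.na(.data$verdict) ~ .data$verdict,
    .data$p_adjusted < alpha ~ "monoallelic",
    TRUE ~ "biallelic"))
}

#' Link significant monoallelic SNPs to nearby ASM sites
#'
#' A significant monoallelic SNP is retained iff some ASM site midpoint lies
#' within `max_distance` of the SNP; the nearest qualifying site is
#' recorded.
#'
#' @param calls Output of [call_monoallelic()] (rows with
#'   `verdict == "monoallelic"` are considered).
#' @param asm_sites Output of [call_asm_sites()] / [annotate_asm_sites()].
#' @param max_distance Maximum SNP-to-site-midpoint distance, bp
#'   (default 1,000,000).
#' @return The linked subset of significant calls, with `asm_site_id` and
#'   `asm_distance` columns.
#' @export
link_candidates_to_asm <- function(calls, asm_sites, max_distance = 1e6) {
  sig <- calls[!is.na(calls$verdict) & calls$verdict == "monoallelic", ]
  if (nrow(sig) == 0L || nrow(asm_sites) == 0L) {
    return(dplyr::mutate(sig[integer(0), ], asm_site_id = character(),
                         asm_distance = numeric()))
  }
  mid <- (asm_sites$start + asm_sites$end) / 2
  site_id <- rep(NA_character_, nrow(sig))
  site_dist <- rep(NA_real_, nrow(sig))
  for (ch in unique(sig$chrom)) {
    si <- which(asm_sites$chrom == ch)
    qi <- which(sig$chrom == ch)
    if (length(si) == 0L) next
    d <- abs(outer(sig$pos[qi], mid[si], "-"))
    j <- max.col(-d, ties.method = "first")
    best <- d[cbind(seq_along(qi), j)]
    hit <- best <= max_distance
    site_id[qi[hit]] <- asm_sites$site_id[si][j[hit]]
    site_dist[qi[hit]] <- best[hit]
  }
  out <- dplyr::mutate(sig, asm_site_id = site_id, asm_distance = site_dist)
  out[!is.na(out$asm_site_id), ]
}

#' Screen gene-level imprinting candidates
#'
#' A gene is a candidate iff at least one sample both (a) supplies a linked
#' significant monoallelic SNP in the gene and (b) shows no biallelic SNP in
#' the gene, where biallelic means per-SNP counts pooled across that
#' sample's tissues reach `min_depth` with minor-allele fraction
#' `>= biallelic_minor_fraction`. Genes whose every supporting sample is
#' contradicted are excluded, carrying the offending SNP as the reason.
#' Pooling is within sample: the expressed parental allele is `ref` in some
#' individuals and `alt` in others, so cross-individual pooling would erase
#' a true imprinting signal.
#'
#' @param linked Output of [link_candidates_to_asm()].
#' @param calls All calls from [call_monoallelic()] (the same screen).
#' @param biallelic_minor_fraction Minor-fraction threshold marking a SNP as
#'   biallelically expressed (default 0.2).
#' @param min_depth Minimum pooled depth for the biallelic check
#'   (default 10).
#' @return Tibble per gene ever supported: `gene_id`, `n_monoallelic_snps`,
#'   `n_supporting_samples`, `asm_site_id`, `excluded`, `exclusion_snp`.
#' @export
screen_gene_candidates <- function(linked, calls,
                                   biallelic_minor_fraction = 0.2,
                                   min_depth = 10L) {
  empty <- tibble::tibble(gene_id = character(),
                          n_monoallelic_snps = integer(),
                          n_supporting_samples = integer(),
                          asm_site_id = character(),
                          excluded = logical(),
                          exclusion_snp = character())
  if (nrow(linked) == 0L) return(empty)
  has_sample <- "sample" %in% names(calls)
  pool_by <- c("gene_id", if (has_sample) "sample", "chrom", "pos")
  pooled <- calls |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(pool_by))) |>
    dplyr::summarise(ref_count = sum(.data$ref_count),
                     alt_count = sum(.data$alt_count), .groups = "drop") |>
    dplyr::mutate(
      depth = .data$ref_count + .data$alt_count,
      minor_fraction = ifelse(.data$depth > 0,
                              pmin(.data$ref_count, .data$alt_count) /
                                .data$depth, NA_real_),
      biallelic = .data$depth >= min_depth &
        .data$minor_fraction >= biallelic_minor_fraction)
  conflict_by <- c("gene_id", if (has_sample) "sample")
  conflicts <- pooled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(conflict_by))) |>
    dplyr::summarise(
      conflicted = any(.data$biallelic),
      offending = if (any(.data$biallelic))
        paste0(.data$chrom[.data$biallelic][1], ":",
               .data$pos[.data$biallelic][1]) else NA_character_,
      .groups = "drop")
  support <- linked |>
    dplyr::group_by(dplyr::across(dplyr::all_of(conflict_by))) |>
    dplyr::summarise(n_snps = dplyr::n_distinct(.data$pos),
                     asm_site_id = .data$asm_site_id[1], .groups = "drop") |>
    dplyr::left_join(conflicts, by = conflict_by) |>
    dplyr::mutate(conflicted = dplyr::coalesce(.data$conflicted, FALSE))
  support |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_monoallelic_snps = as.integer(max(.data$n_snps)),
      n_supporting_samples = sum(!.data$conflicted),
      asm_site_id = .data$asm_site_id[1],
      excluded = all(.data$conflicted),
      exclusion_snp = if (all(.data$conflicted))
        .data$offending[1] else NA_character_,
      .groups = "drop") |>
    dplyr::arrange(.data$gene_id)
}

#' Genotype an amplicon from deep allele counts
#'
#' Heterozygous iff both allele fractions reach `min_variant_fraction`
#' (a fraction of exactly the threshold qualifies); otherwise homozygous for
#' the majority allele. Zero depth gives a no-call (NA).
#'
#' @param ref_count,alt_count Allele read counts (vectorised).
#' @param min_variant_fraction Detection threshold (default 0.2).
#' @return Character vector in `hom_ref`, `het`, `hom_alt`, or NA.
#' @export
amplicon_genotype <- function(ref_count, alt_count,
                              min_variant_fraction = 0.2) {
  depth <- ref_count + alt_count
  fr <- ref_count / depth
  fa <- alt_count / depth
  out <- ifelse(fr >= min_variant_fraction & fa >= min_variant_fraction,
                "het",
                ifelse(ref_count >= alt_count, "hom_ref", "hom_alt"))
  out[depth == 0] <- NA_character_
  out
}
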