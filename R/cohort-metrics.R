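# Cohort-level metrics: variant quality filtering, standardised multilocus
# heterozygosity (sMLH), group comparison, and the weaning-signature
# (galactase/CYP) expression screen.

#' Filter variant records on quality, depth and missingness
#'
#' Keeps records with `quality >= min_quality`, `mean_depth >=
#' min_mean_depth` and missing-call fraction at most
#' `max_missing_fraction` (all bounds inclusive). Idempotent.
#'
#' @param records Tibble with `quality`, `mean_depth` and
#'   `missing_fraction` columns.
#' @param min_quality Minimum site quality (default 30).
#' @param min_mean_depth Minimum mean depth (default 10).
#' @param max_missing_fraction Maximum fraction of uncalled samples
#'   (default 0.05, i.e. called in at least 95% of samples).
#' @return The filtered tibble.
#' @export
filter_variants <- function(records, min_quality = 30, min_mean_depth = 10,
                            max_missing_fraction = 0.05) {
  records[records$quality >= min_quality &
            records$mean_depth >= min_mean_depth &
            records$missing_fraction <= max_missing_fraction, ]
}

#' Standardised multilocus heterozygosity per sample
#'
#' `sMLH_i` is the number of heterozygous loci of sample `i` divided by the
#' sum, over the loci typed in `i`, of the across-sample observed
#' heterozygote frequency of each locus. Missing genotypes are excluded
#' from both the numerator and the locus set, so samples typed at different
#' loci remain comparable. With complete data the sample mean of sMLH is
#' exactly 1.
#'
#' @param genotypes Long tibble: `sample`, `locus`, `genotype`
#'   (`hom_ref`/`het`/`hom_alt`, NA = missing).
#' @return Tibble per sample: `n_typed`, `n_het`, `smlh` (NA for samples
#'   with no typed locus).
#' @export
compute_smlh <- function(genotypes) {
  g <- dplyr::mutate(genotypes, het = .data$genotype == "het")
  locus_h <- g |>
    dplyr::filter(!is.na(.data$het)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(h_bar = mean(.data$het), .groups = "drop")
  g |>
    dplyr::left_join(locus_h, by = "locus") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_typed = sum(!is.na(.data$het)),
      n_het = sum(.data$het, na.rm = TRUE),
      denom = sum(.data$h_bar[!is.na(.data$het)]),
      .groups = "drop") |>
    dplyr::mutate(smlh = ifelse(.data$n_typed > 0 & .data$denom > 0,
                                .data$n_het / .data$denom, NA_real_)) |>
    dplyr::select(-"denom")
}

#' Compare sMLH between groups by Wilcoxon rank-sum
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups: exact when
#' the combined sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with continuity correction (ties mid-ranked).
#' Size-0 groups are skipped with a warning; size-1 groups are tested but
#' best read descriptively.
#'
#' @param values Numeric vector (e.g. per-sample sMLH).
#' @param groups Group label per value.
#' @return Tibble per group pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (Wilcoxon W), `p`, `exact`.
#' @export
compare_smlh_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  lev <- unique(groups)
  sizes <- table(factor(groups, levels = lev))
  if (any(sizes == 0)) {
    rlang::warn(paste("skipping empty group(s):",
                      paste(names(sizes)[sizes == 0], collapse = ", ")))
    lev <- names(sizes)[sizes > 0]
  }
  if (length(lev) < 2) stop("need at least 2 non-empty groups")
  pairs <- utils::combn(lev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- values[groups == pairs[1, k]]
    b <- values[groups == pairs[2, k]]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- (length(a) + length(b)) <= 20 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    tibble::tibble(group1 = pairs[1, k], group2 = pairs[2, k],
                   n1 = length(a), n2 = length(b),
                   statistic = unname(wt$statistic), p = wt$p.value,
                   exact = exact)
  })
  dplyr::bind_rows(out)
}

#' Log2 RPKM expression values
#'
#' `RPKM = count * 1e9 / (gene length in bp * library size in reads)`,
#' with `pseudocount` added to the count before scaling so zeros stay
#' finite on the log2 scale.
#'
#' @param counts Long tibble: `gene_id`, `sample`, `count` (an optional
#'   `tissue` column is treated as part of the sample unit).
#' @param gene_lengths Tibble `gene_id`, `length_bp`.
#' @param library_sizes Optional tibble `sample` (`tissue`), `library_size`;
#'   defaults to the per-sample total of `counts`.
#' @param pseudocount Reads added to each count (default 1).
#' @return `counts` with `rpkm` and `log2_rpkm` columns.
#' @export
log2_rpkm <- function(counts, gene_lengths, library_sizes = NULL,
                      pseudocount = 1) {
  unit <- intersect(c("sample", "tissue"), names(counts))
  if (is.null(library_sizes)) {
    library_sizes <- counts |>
      dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
      dplyr::summarise(library_size = sum(.data$count), .groups = "drop")
  }
  if (any(gene_lengths$length_bp <= 0))
    stop("zero-length gene in `gene_lengths`")
  if (any(library_sizes$library_size <= 0))
    stop("non-positive library size")
  counts |>
    dplyr::left_join(gene_lengths, by = "gene_id") |>
    dplyr::left_join(library_sizes,
                     by = intersect(unit, names(library_sizes))) |>
    dplyr::mutate(
      rpkm = (.data$count + pseudocount) * 1e9 /
        (.data$length_bp * .data$library_size),
      log2_rpkm = log2(.data$rpkm)) |>
    dplyr::select(-"length_bp", -"library_size")
}

#' Galactase/CYP weaning-signature ratio per sample
#'
#' The difference between the mean log2 RPKM of the galactase gene set and
#' of the CYP gene set (a log-scale ratio of geometric means). High values
#' are pre-weaning-like (milk digestion); low values indicate weaning.
#' Invariant to adding a constant to every expression value.
#'
#' @param expr Long expression tibble with `gene_id`, `log2_rpkm` and the
#'   sample unit columns (`sample`, optional `tissue`).
#' @param gal_genes,cyp_genes Character vectors of gene ids (user-supplied
#'   set membership).
#' @return Tibble per sample unit: `gal_mean`, `cyp_mean`, `ratio`.
#' @export
gal_cyp_ratio <- function(expr, gal_genes, cyp_genes) {
  missing <- setdiff(c(gal_genes, cyp_genes), unique(expr$gene_id))
  if (length(missing) > 0)
    stop("gene set members absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(gal_genes) == 0 || length(cyp_genes) == 0)
    stop("both gene sets must be non-empty")
  unit <- intersect(c("sample", "tissue"), names(expr))
  expr |>
    dplyr::filter(.data$gene_id %in% c(gal_genes, cyp_genes)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
    dplyr::summarise(
      gal_mean = mean(.data$log2_rpkm[.data$gene_id %in% gal_genes]),
      cyp_mean = mean(.data$log2_rpkm[.data$gene_id %in% cyp_genes]),
      .groups = "drop") |>
    dplyr::mutate(ratio = .data$gal_mean - .data$cyp_mean)
}

#' Rank genes by correlation with the weaning-signature ratio
#'
#' Per-gene Spearman correlation (rank-based, hence invariant to monotone
#' transforms of expression) with the per-sample ratio vector, ranked
#' descending; anti-correlated genes are flagged. Constant genes have
#' undefined correlation and are reported with a missing value.
#'
#' @param expr Long expression tibble (`gene_id`, `log2_rpkm`, sample unit
#'   columns).
#' @param ratio Output of [gal_cyp_ratio()] (or any tibble with the sample
#'   unit columns and a `ratio` column).
#' @param method Correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @return Tibble per gene: `correlation`, `rank` (1 = most correlated),
#'   `anti_correlated`.
#' @export
signature_correlation <- function(expr, ratio,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  unit <- intersect(c("sample", "tissue"), names(expr))
  joined <- dplyr::inner_join(expr, ratio[, c(unit, "ratio")], by = unit)
  n_units <- nrow(dplyr::distinct(joined[, unit]))
  if (n_units < 3) stop("need at least 3 samples")
  res <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      correlation = if (stats::sd(.data$log2_rpkm) == 0) NA_real_ else
        stats::cor(.data$log2_rpkm, .data$ratio, method = method),
      .groups = "drop")
  res |>
    dplyr::arrange(dplyr::desc(.data$correlation)) |>
    dplyr::mutate(rank = ifelse(is.na(.data$correlation), NA_integer_,
                                dplyr::row_number()),
                  anti_correlated = !is.na(.data$correlation) &
                    .data$correlation < 0)
}
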