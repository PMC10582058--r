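# Germline reprogramming: global methylation quantitation, library QC,
# developmental stage grouping, group testing, region methylation over ASM
# sites and the germline ICR screen.

#' Global CpG methylation of bisulfite libraries
#'
#' The proportion of methylated CG calls over total CG calls, as a percent.
#'
#' @param libraries Tibble with `cg_methylated` and `cg_total` columns.
#' @return `libraries` with a `global_methylation` percent column.
#' @export
global_methylation <- function(libraries) {
  if (any(libraries$cg_total < 1))
    stop("QC failure: library with zero CG calls has undefined methylation")
  dplyr::mutate(libraries,
                global_methylation = 100 * .data$cg_methylated /
                  .data$cg_total)
}

#' Bisulfite library quality control
#'
#' Fails libraries with fewer than `min_cg_calls` CG calls or mapping
#' efficiency strictly below `min_mapping` percent. Bisulfite conversion
#' efficiency is estimated from residual non-CpG methylation as
#' `100 - non-CG methylation %`.
#'
#' @param libraries Tibble with `cg_total`, `mapping_efficiency`,
#'   `noncg_methylated`, `noncg_total`.
#' @param min_cg_calls Minimum CG calls (default 400).
#' @param min_mapping Minimum mapping efficiency percent (default 35).
#' @return `libraries` with `conversion_efficiency`, `qc_pass` and
#'   `qc_reason` columns.
#' @export
library_qc <- function(libraries, min_cg_calls = 400L, min_mapping = 35) {
  conv <- ifelse(libraries$noncg_total > 0,
                 100 - 100 * libraries$noncg_methylated /
                   libraries$noncg_total, NA_real_)
  low_cg <- libraries$cg_total < min_cg_calls
  low_map <- libraries$mapping_efficiency < min_mapping
  reason <- dplyr::case_when(
    low_cg & low_map ~ "low CG calls; low mapping efficiency",
    low_cg ~ "low CG calls",
    low_map ~ "low mapping efficiency",
    TRUE ~ NA_character_)
  dplyr::mutate(libraries, conversion_efficiency = conv,
                qc_pass = !low_cg & !low_map, qc_reason = reason)
}

#' Group germline libraries by developmental stage
#'
#' PGC libraries are grouped by days postpartum: `pre` methylation loss
#' below 10 dpp, `demethylated` at 13-16 dpp, `remethylated` above 16 dpp.
#' Ages falling in the 10-13 dpp gap, where the stage bands do not tile,
#' are surfaced as `unclassified` rather than silently assigned. Somatic
#' and sperm libraries pass their cell-type label through.
#'
#' @param libraries Tibble with `cell_type` (`PGC`/`soma`/`sperm`) and
#'   `stage_dpp` columns.
#' @return `libraries` with a `stage_group` column.
#' @export
assign_stage <- function(libraries) {
  grp <- ifelse(
    libraries$cell_type == "soma", "soma",
    ifelse(libraries$cell_type == "sperm", "sperm",
           ifelse(libraries$stage_dpp < 10, "pre",
                  ifelse(libraries$stage_dpp >= 13 &
                           libraries$stage_dpp <= 16, "demethylated",
                         ifelse(libraries$stage_dpp > 16, "remethylated",
                                "unclassified")))))
  if (any(grp == "unclassified", na.rm = TRUE))
    rlang::warn("assign_stage: PGC libraries at 10-13 dpp fall in the gap between stage bands and were left unclassified")
  dplyr::mutate(libraries, stage_group = grp)
}

#' Welch two-sample t-test on methylation percentages
#'
#' Two-sample t-test with unequal variances (Welch-Satterthwaite degrees of
#' freedom), two-sided.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return Tibble with `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(tibble::tibble(t = 0, df = NA_real_, p = 1))
    return(tibble::tibble(t = sign(mean(group_a) - mean(group_b)) * Inf,
                          df = NA_real_, p = 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

#' Pooled methylation of ASM sites per library
#'
#' Per library and site, methylated and total calls are pooled over the
#' CpGs falling inside the site that have at least `min_reads` calls.
#' Per-read call tables (rows with a `read_id` and 0/1 `methylated`) are
#' first deduplicated on (library, read, position) and aggregated;
#' pre-aggregated tables (`methylated`, `total` counts) are used as is.
#' Sites with no covered CpG in a library get a missing percent, never
#' zero.
#'
#' @param calls Per-CpG calls: `library_id`, `chrom`, `pos`, plus either
#'   (`methylated`, `total`) counts or per-read rows (`read_id`,
#'   `methylated` 0/1).
#' @param asm_sites Sites with `site_id`, `chrom`, `start`, `end`
#'   (0-based half-open, as from [call_asm_sites()]).
#' @param min_reads Minimum calls per CpG (default 1).
#' @return Tibble per library x site: `methylated`, `total`, `percent`
#'   (NA when uncovered).
#' @export
region_methylation <- function(calls, asm_sites, min_reads = 1L) {
  if ("read_id" %in% names(calls)) {
    calls <- calls |>
      dplyr::distinct(.data$library_id, .data$read_id, .data$chrom,
                      .data$pos, .keep_all = TRUE) |>
      dplyr::group_by(.data$library_id, .data$chrom, .data$pos) |>
      dplyr::summarise(methylated = sum(.data$methylated),
                       total = dplyr::n(), .groups = "drop")
  }
  calls <- calls[calls$total >= min_reads, ]
  site_of <- rep(NA_character_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    si <- which(asm_sites$chrom == ch)
    qi <- which(calls$chrom == ch)
    if (length(si) == 0L) next
    hit <- match_point_to_interval(calls$pos[qi],
                                   asm_sites$start[si] + 1L,
                                   asm_sites$end[si])
    site_of[qi] <- asm_sites$site_id[si][hit]
  }
  calls$site_id <- site_of
  observed <- calls |>
    dplyr::filter(!is.na(.data$site_id)) |>
    dplyr::group_by(.data$library_id, .data$site_id) |>
    dplyr::summarise(methylated = sum(.data$methylated),
                     total = sum(.data$total), .groups = "drop")
  grid <- tidyr::expand_grid(library_id = unique(calls$library_id),
                             site_id = asm_sites$site_id)
  grid |>
    dplyr::left_join(observed, by = c("library_id", "site_id")) |>
    dplyr::mutate(percent = ifelse(!is.na(.data$total) & .data$total >= 1,
                                   100 * .data$methylated / .data$total,
                                   NA_real_))
}

#' Screen ASM sites for germline imprint-control-region behaviour
#'
#' A site is `not_ICR_like` unless its somatic methylation lies inside
#' `soma_band` (inclusive on both ends), the range germline ICRs occupy in
#' somatic tissue (one parental allele methylated). ICR-like sites are then
#' split by sperm methylation: at or below `sperm_low` percent means the
#' mark is erased in sperm and must be carried by the oocyte
#' (`maternal_ICR`); at or above `sperm_high` means sperm carries the mark
#' (`paternal_ICR`); in between, `erased_only`. Demethylated-stage PGC
#' methylation is reported alongside as erasure evidence.
#'
#' @param site_methylation Tibble per site: `site_id`, `soma_percent`,
#'   `pgc_percent`, `sperm_percent` (see [region_methylation()]).
#' @param soma_band Somatic inclusion band in percent (default `c(30, 57)`).
#' @param sperm_low,sperm_high Sperm thresholds in percent (defaults 20
#'   and 80).
#' @return `site_methylation` with a `verdict` column in `maternal_ICR`,
#'   `paternal_ICR`, `erased_only`, `not_ICR_like` (NA when somatic
#'   methylation is missing).
#' @export
screen_icr_candidates <- function(site_methylation, soma_band = c(30, 57),
                                  sperm_low = 20, sperm_high = 80) {
  s <- site_methylation
  verdict <- dplyr::case_when(
    is.na(s$soma_percent) ~ NA_character_,
    s$soma_percent < soma_band[1] | s$soma_percent > soma_band[2] ~
      "not_ICR_like",
    !is.na(s$sperm_percent) & s$sperm_percent <= sperm_low ~ "maternal_ICR",
    !is.na(s$sperm_percent) & s$sperm_percent >= sperm_high ~
      "paternal_ICR",
    TRUE ~ "erased_only")
  dplyr::mutate(s, verdict = verdict)
}
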