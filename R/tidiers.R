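# broom-style accessors and ggplot2 methods for scan results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an imprint scan into its per-gene calls
#'
#' One row per screened gene: candidate status, parent-of-origin call, duo
#' evidence counts and Hardy-Weinberg support.
#'
#' @param x An `imprint_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy imprint_scan
#' @export
tidy.imprint_scan <- function(x, ...) {
  out <- dplyr::left_join(x$gene_screen, x$imprint_calls, by = "gene_id")
  out$status[is.na(out$status)] <- "insufficient"
  out
}

#' One-row summary of an imprint scan
#'
#' @param x An `imprint_scan`.
#' @param ... Unused.
#' @return A one-row tibble: phase blocks, ASM sites, candidates, confirmed
#'   parent-of-origin calls, conflicting calls, ICR-like sites.
#' @method glance imprint_scan
#' @export
glance.imprint_scan <- function(x, ...) {
  st <- x$imprint_calls$status
  tibble::tibble(
    n_phase_blocks = length(unique(x$blocks$block_id)),
    n_asm_sites = nrow(x$asm_sites),
    n_candidate_genes = nrow(x$candidates),
    n_parent_calls = sum(st %in% c("maternal_expressed",
                                   "paternal_expressed")),
    n_conflicting = sum(st == "conflicting"),
    n_icr_like = if (is.null(x$icr_screen)) NA_integer_ else
      sum(x$icr_screen$verdict %in% c("maternal_ICR", "paternal_ICR"),
          na.rm = TRUE))
}

#' Plot duo evidence per candidate gene
#'
#' Stacked bars of informative mother-offspring duos per gene, split by the
#' parental origin of the expressed allele, annotated with the final call.
#'
#' @param object An `imprint_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot imprint_scan
#' @export
autoplot.imprint_scan <- function(object, ...) {
  calls <- object$imprint_calls
  if (nrow(calls) == 0)
    stop("no imprint calls to plot")
  long <- calls |>
    tidyr::pivot_longer(c("n_maternal", "n_paternal"),
                        names_to = "origin", values_to = "n_duos") |>
    dplyr::mutate(origin = sub("^n_", "", .data$origin))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene_id, y = .data$n_duos,
                                     fill = .data$origin)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ status, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(maternal = "#D55E00",
                                          paternal = "#0072B2")) +
    ggplot2::labs(x = NULL, y = "informative duos",
                  fill = "expressed allele origin") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the germline methylation trajectory
#'
#' Global CpG methylation against days postpartum for PGC libraries, with
#' somatic and sperm libraries alongside: the erase-and-re-establish
#' reprogramming curve of the male germline.
#'
#' @param libraries Library tibble (see [make_germline_libraries()] or
#'   [global_methylation()]); `global_methylation` is computed if absent.
#' @return A ggplot.
#' @export
plot_germline_trajectory <- function(libraries) {
  if (!"global_methylation" %in% names(libraries))
    libraries <- global_methylation(libraries)
  pgc <- libraries[libraries$cell_type == "PGC", ]
  other <- libraries[libraries$cell_type != "PGC", ]
  other$x <- ifelse(other$cell_type == "sperm",
                    max(pgc$stage_dpp, na.rm = TRUE) + 10, other$stage_dpp)
  ggplot2::ggplot(pgc, ggplot2::aes(x = .data$stage_dpp,
                                    y = .data$global_methylation)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = "PGC"), size = 2) +
    ggplot2::geom_point(data = other,
                        ggplot2::aes(x = .data$x,
                                     colour = .data$cell_type), size = 2) +
    ggplot2::scale_colour_manual(values = c(PGC = "#009E73",
                                            soma = "#56B4E9",
                                            sperm = "#CC79A7")) +
    ggplot2::labs(x = "days postpartum", y = "global CpG methylation (%)",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_bw()
}

#' Plot per-haplotype methylation around ASM sites
#'
#' Haplotype methylation fractions of the CpGs in a genomic window,
#' the per-CpG view in which allele-specific methylation appears as two
#' separated bands.
#'
#' @param counts Output of [haplotype_methylation_counts()].
#' @param chrom,start,end Window to draw.
#' @return A ggplot.
#' @export
plot_methylation_haplotypes <- function(counts, chrom, start, end) {
  d <- counts[counts$chrom == chrom & counts$pos >= start &
                counts$pos <= end, ]
  long <- dplyr::bind_rows(
    tibble::tibble(pos = d$pos, hap = "hap1",
                   fraction = d$hap1_meth / pmax(d$hap1_total, 1)),
    tibble::tibble(pos = d$pos, hap = "hap2",
                   fraction = d$hap2_meth / pmax(d$hap2_total, 1)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$fraction,
                                     colour = .data$hap)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(hap1 = "#E69F00",
                                            hap2 = "#56B4E9")) +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom),
                  y = "methylated fraction", colour = NULL) +
    ggplot2::theme_bw()
}
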