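# Synthetic cohort generator: reference panel, phased diploid cohort with
# mother-offspring duos, methylation-bearing long reads, allelic RNA counts
# and a germline bisulfite series, all with a machine-readable truth set.

#' Build the synthetic reference panel
#'
#' Lays out chromosomes, background CpGs, a promoter CpG island upstream of
#' every gene, panel SNPs with population allele frequencies, and gene
#' models. SNP and CpG coordinates never collide. Imprint control regions are
#' chosen later (by [make_cohort()]) among the gene islands.
#'
#' @param config A [sim_config()].
#' @return A `reference_panel` list with tibbles `chromosomes`, `cpgs`,
#'   `snps` and `genes`.
#' @export
make_reference_panel <- function(config) {
  validate_sim_config(config)
  island_len <- 1200L
  island_gap <- 800L
  if (config$icr_cpg_count > island_len)
    stop("sizing error: `icr_cpg_count` (", config$icr_cpg_count,
         ") exceeds the ", island_len, " bp island that must hold it")
  with_seed(subseed(config$seed, "panel"), {
    nchr <- config$n_chromosomes
    L <- as.integer(config$chrom_length)
    chrom_names <- paste0("chr", seq_len(nchr))
    chromosomes <- tibble::tibble(chrom = chrom_names, length = L)

    # genes: distributed over chromosomes on jittered non-overlapping slots,
    # each preceded by its promoter island
    per_chrom <- rep(config$n_genes %/% nchr, nchr)
    extra <- config$n_genes %% nchr
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    unit <- config$gene_length + island_len + island_gap
    # genes stay one read length clear of the chromosome ends, where
    # uniformly placed reads cannot reach full coverage
    margin <- min(config$read_length, L %/% 4L)
    gene_rows <- list()
    gid <- 0L
    for (ci in seq_len(nchr)) {
      k <- per_chrom[ci]
      if (k == 0L) next
      w <- (L - 2L * margin) %/% k
      if (w < unit + 1L)
        stop("sizing error: chromosome length ", L, " bp cannot hold ", k,
             " genes of ", config$gene_length,
             " bp each with their promoter islands plus the ", margin,
             " bp end margins (needs >= ", k * (unit + 1L) + 2L * margin,
             " bp)")
      jitter <- sample.int(w - unit, k, replace = TRUE)
      slot0 <- margin + (seq_len(k) - 1L) * w
      start <- slot0 + island_len + island_gap + jitter
      end <- start + config$gene_length - 1L
      gene_rows[[ci]] <- tibble::tibble(
        gene_id = sprintf("g%04d", gid + seq_len(k)),
        chrom = chrom_names[ci],
        start = start, end = end,
        strand = sample(c("+", "-"), k, replace = TRUE),
        exon_start = start, exon_end = end,
        island_start = start - island_gap - island_len,
        island_end = start - island_gap - 1L
      )
      gid <- gid + k
    }
    genes <- if (length(gene_rows)) dplyr::bind_rows(gene_rows) else
      tibble::tibble(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     exon_start = integer(), exon_end = integer(),
                     island_start = integer(), island_end = integer())

    # CpG track: Poisson background plus dense promoter islands
    cpg_rows <- list()
    for (ci in seq_len(nchr)) {
      nb <- stats::rpois(1, L * config$cpg_density / 1000)
      pos <- sample.int(L, min(nb, L))
      gi <- genes[genes$chrom == chrom_names[ci], ]
      if (nrow(gi) > 0) {
        island_pos <- unlist(lapply(seq_len(nrow(gi)), function(r) {
          gi$island_start[r] - 1L +
            sample.int(island_len, config$icr_cpg_count)
        }))
        pos <- c(pos, island_pos)
      }
      cpg_rows[[ci]] <- tibble::tibble(chrom = chrom_names[ci],
                                       pos = sort(unique(pos)))
    }
    cpgs <- dplyr::bind_rows(cpg_rows)

    # SNP track: Poisson positions avoiding CpGs, topped up so every gene
    # carries at least `exonic_snps_per_gene` exonic SNPs
    snp_rows <- list()
    bases <- c("A", "C", "G", "T")
    for (ci in seq_len(nchr)) {
      cpg_pos <- cpgs$pos[cpgs$chrom == chrom_names[ci]]
      ns <- stats::rpois(1, L * config$snp_density / 1000)
      pos <- setdiff(sample.int(L, min(ns, L)), cpg_pos)
      gi <- genes[genes$chrom == chrom_names[ci], ]
      if (nrow(gi) > 0 && config$exonic_snps_per_gene > 0) {
        for (r in seq_len(nrow(gi))) {
          span <- gi$exon_start[r]:gi$exon_end[r]
          have <- sum(pos >= gi$exon_start[r] & pos <= gi$exon_end[r])
          need <- config$exonic_snps_per_gene - have
          if (need > 0) {
            free <- setdiff(span, c(cpg_pos, pos))
            pos <- c(pos, sample(free, min(need, length(free))))
          }
        }
      }
      pos <- sort(unique(pos))
      ref <- sample(bases, length(pos), replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      snp_rows[[ci]] <- tibble::tibble(
        chrom = chrom_names[ci], pos = pos, ref = ref, alt = unname(alt),
        freq = stats::runif(length(pos), 0.2, 0.8)
      )
    }
    snps <- dplyr::bind_rows(snp_rows)

    structure(list(chromosomes = chromosomes, cpgs = cpgs, snps = snps,
                   genes = genes),
              class = "reference_panel")
  })
}

#' Simulate a phased diploid cohort with duos and the imprinting truth set
#'
#' Founders draw both haplotypes from the panel allele frequencies; each
#' non-founder inherits one complete maternal chromosome haplotype from a
#' sampled mother (Mendelian by construction) and a population paternal
#' haplotype (fathers are unsampled, matching a wild-caught study design).
#' `n_icrs` genes are declared imprinted: their promoter island becomes an
#' ICR whose methylated parental allele silences the gene in cis, so the
#' expressed parent is the opposite of the methylated parent.
#'
#' @param panel A [make_reference_panel()] result.
#' @param config The same [sim_config()].
#' @return A `sim_cohort` list: `genotypes` (wide tibble, one phased
#'   `maternal|paternal` column per sample), `truth` (ICRs, imprinted genes,
#'   haplotype matrices, pedigree), `samples`.
#' @export
make_cohort <- function(panel, config) {
  validate_sim_config(config)
  with_seed(subseed(config$seed, "cohort"), {
    n <- config$n_individuals
    k <- round(config$fraction_with_mother * n)
    if (k > 0 && n < 2)
      stop("pedigree error: cannot create duos with fewer than 2 individuals")
    k <- min(k, n - 1L)
    samples <- sprintf("ind%03d", seq_len(n))
    founders <- samples[seq_len(n - k)]
    mothers <- if (k > 0) sample(founders, k, replace = TRUE) else character()
    pedigree <- tibble::tibble(
      sample = samples,
      mother = c(rep(NA_character_, n - k), mothers)
    )

    nsnp <- nrow(panel$snps)
    freq <- panel$snps$freq
    mat <- matrix(stats::rbinom(nsnp * n, 1L, rep(freq, n)), nsnp, n)
    pat <- matrix(stats::rbinom(nsnp * n, 1L, rep(freq, n)), nsnp, n)
    colnames(mat) <- colnames(pat) <- samples
    chrom_of <- panel$snps$chrom
    for (child in which(!is.na(pedigree$mother))) {
      mcol <- match(pedigree$mother[child], samples)
      for (ch in unique(chrom_of)) {
        rows <- which(chrom_of == ch)
        src <- if (stats::runif(1) < 0.5) mat else pat
        mat[rows, child] <- src[rows, mcol]
      }
    }

    # imprinting truth: promoter islands of sampled genes become ICRs.
    # Distinct imprinted loci are kept >= 25 kb apart: genomic imprinted
    # clusters closer than that share a single control region, which the
    # truth model represents as one ICR.
    if (config$n_icrs > 0) {
      min_sep <- 25000
      cand <- sample.int(nrow(panel$genes))
      imp <- integer()
      for (gi in cand) {
        same <- imp[panel$genes$chrom[imp] == panel$genes$chrom[gi]]
        if (length(same) == 0L ||
            all(abs(panel$genes$start[same] - panel$genes$start[gi]) >=
                  min_sep))
          imp <- c(imp, gi)
        if (length(imp) == config$n_icrs) break
      }
      if (length(imp) < config$n_icrs)
        stop("sizing error: cannot place ", config$n_icrs,
             " imprinted loci at >= ", min_sep, " bp separation; ",
             "use fewer ICRs or a larger genome")
      imp <- sort(imp)
      g <- panel$genes[imp, ]
      nm <- round(config$fraction_maternal_methylated_icrs * config$n_icrs)
      meth_parent <- sample(c(rep("maternal", nm),
                              rep("paternal", config$n_icrs - nm)))
      nl <- round(config$leaky_fraction * config$n_icrs)
      leaky <- seq_len(config$n_icrs) %in% sample.int(config$n_icrs, nl)
      icrs <- tibble::tibble(
        icr_id = sprintf("icr%02d", seq_len(config$n_icrs)),
        chrom = g$chrom, start = g$island_start, end = g$island_end,
        methylated_parent = meth_parent, gene_id = g$gene_id
      )
      imprinted_genes <- tibble::tibble(
        gene_id = g$gene_id,
        expressed_parent = ifelse(meth_parent == "maternal",
                                  "paternal", "maternal"),
        icr_id = icrs$icr_id,
        leaky = leaky,
        minor_fraction = ifelse(leaky, config$leaky_minor_fraction, 0)
      )
    } else {
      icrs <- tibble::tibble(icr_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             methylated_parent = character(),
                             gene_id = character())
      imprinted_genes <- tibble::tibble(gene_id = character(),
                                        expressed_parent = character(),
                                        icr_id = character(),
                                        leaky = logical(),
                                        minor_fraction = numeric())
    }

    gt_cols <- lapply(seq_len(n), function(i) paste0(mat[, i], "|", pat[, i]))
    names(gt_cols) <- samples
    genotypes <- dplyr::bind_cols(
      panel$snps[, c("chrom", "pos", "ref", "alt")],
      tibble::as_tibble(gt_cols)
    )

    truth <- structure(list(
      icrs = icrs, imprinted_genes = imprinted_genes,
      haplotypes = list(maternal = mat, paternal = pat,
                        snps = panel$snps[, c("chrom", "pos")],
                        samples = samples),
      pedigree = pedigree
    ), class = "synthetic_truth")

    structure(list(genotypes = genotypes, truth = truth, samples = samples),
              class = "sim_cohort")
  })
}

# Per-CpG methylation probability on each parental haplotype: background
# outside ICRs (promoter islands of non-imprinted genes are hypomethylated
# on both alleles); at an ICR the methylated parent's allele is high, the
# other low.
cpg_parent_probs <- function(panel, truth, config) {
  ncpg <- nrow(panel$cpgs)
  pm <- rep(config$background_methylation, ncpg)
  pp <- rep(config$background_methylation, ncpg)
  g <- panel$genes
  if (nrow(g) > 0) {
    for (ch in unique(g$chrom)) {
      in_ch <- panel$cpgs$chrom == ch
      gi <- g[g$chrom == ch, ]
      hit <- match_point_to_interval(panel$cpgs$pos[in_ch],
                                     gi$island_start, gi$island_end)
      island <- which(in_ch)[!is.na(hit)]
      pm[island] <- 0.15
      pp[island] <- 0.15
    }
  }
  ic <- truth$icrs
  if (nrow(ic) > 0) {
    for (r in seq_len(nrow(ic))) {
      idx <- which(panel$cpgs$chrom == ic$chrom[r] &
                     panel$cpgs$pos >= ic$start[r] &
                     panel$cpgs$pos <= ic$end[r])
      if (ic$methylated_parent[r] == "maternal") {
        pm[idx] <- config$icr_methylated_level
        pp[idx] <- config$icr_unmethylated_level
      } else {
        pm[idx] <- config$icr_unmethylated_level
        pp[idx] <- config$icr_methylated_level
      }
    }
  }
  cbind(maternal = pm, paternal = pp)
}

#' Simulate methylation-bearing long reads for focal individuals
#'
#' Each read originates from one parental haplotype, reports the haplotype's
#' allele at every overlapped SNP (flipped with probability
#' `snp_read_error`) and a Bernoulli per-CpG methylation state drawn from the
#' haplotype's regional methylation probability (flipped with probability
#' `methylation_call_error`). True read origins are returned in a separate
#' truth sidecar, never in the read tables themselves.
#'
#' @param cohort A [make_cohort()] result.
#' @param panel The matching [make_reference_panel()].
#' @param config The same [sim_config()].
#' @param individuals Sample ids to sequence (default: the first sample,
#'   playing the deeply sequenced reference individual).
#' @param truth Truth set (defaults to `cohort$truth`).
#' @return A `sim_reads` list: tibbles `reads`, `read_snps` (alleles coded
#'   0 = ref, 1 = alt), `read_cpgs`, and truth sidecar `origins`.
#' @export
make_long_reads <- function(cohort, panel, config,
                            individuals = cohort$samples[1],
                            truth = cohort$truth) {
  validate_sim_config(config)
  if (config$read_length > config$chrom_length)
    stop("sizing error: `read_length` (", config$read_length,
         ") exceeds `chrom_length` (", config$chrom_length, ")")
  probs <- cpg_parent_probs(panel, truth, config)
  hap_mats <- truth$haplotypes
  with_seed(subseed(config$seed, "reads"), {
    reads_l <- list(); snps_l <- list(); cpgs_l <- list(); orig_l <- list()
    for (ind in individuals) {
      icol <- match(ind, cohort$samples)
      if (is.na(icol)) stop("unknown individual: ", ind)
      for (ci in seq_len(nrow(panel$chromosomes))) {
        ch <- panel$chromosomes$chrom[ci]
        L <- panel$chromosomes$length[ci]
        nr <- max(1L, round(config$read_depth * L / config$read_length))
        start <- sample.int(L - config$read_length + 1L, nr, replace = TRUE)
        end <- start + config$read_length - 1L
        hap <- sample(c("maternal", "paternal"), nr, replace = TRUE)
        rid <- sprintf("%s_%s_r%05d", ind, ch, seq_len(nr))
        reads_l[[length(reads_l) + 1L]] <- tibble::tibble(
          read_id = rid, individual = ind, chrom = ch,
          start = start, end = end)
        orig_l[[length(orig_l) + 1L]] <- tibble::tibble(
          read_id = rid, haplotype = hap)

        snp_idx <- which(panel$snps$chrom == ch)
        if (length(snp_idx) > 0) {
          fo <- IRanges::findOverlaps(
            IRanges::IRanges(panel$snps$pos[snp_idx], width = 1L),
            IRanges::IRanges(start, end))
          si <- snp_idx[S4Vectors::queryHits(fo)]
          ri <- S4Vectors::subjectHits(fo)
          if (length(si) > 0) {
            hm <- hap_mats$maternal[si, icol]
            hp <- hap_mats$paternal[si, icol]
            allele <- ifelse(hap[ri] == "maternal", hm, hp)
            flip <- stats::rbinom(length(allele), 1L, config$snp_read_error)
            snps_l[[length(snps_l) + 1L]] <- tibble::tibble(
              read_id = rid[ri], chrom = ch, pos = panel$snps$pos[si],
              allele = as.integer((allele + flip) %% 2L))
          }
        }

        cpg_idx <- which(panel$cpgs$chrom == ch)
        if (length(cpg_idx) > 0) {
          fo <- IRanges::findOverlaps(
            IRanges::IRanges(panel$cpgs$pos[cpg_idx], width = 1L),
            IRanges::IRanges(start, end))
          qi <- cpg_idx[S4Vectors::queryHits(fo)]
          ri <- S4Vectors::subjectHits(fo)
          if (length(qi) > 0) {
            p <- ifelse(hap[ri] == "maternal",
                        probs[qi, "maternal"], probs[qi, "paternal"])
            state <- stats::rbinom(length(p), 1L, p)
            flip <- stats::rbinom(length(p), 1L,
                                  config$methylation_call_error)
            cpgs_l[[length(cpgs_l) + 1L]] <- tibble::tibble(
              read_id = rid[ri], chrom = ch, pos = panel$cpgs$pos[qi],
              methylated = as.integer((state + flip) %% 2L))
          }
        }
      }
    }
    structure(list(reads = dplyr::bind_rows(reads_l),
                   read_snps = dplyr::bind_rows(snps_l),
                   read_cpgs = dplyr::bind_rows(cpgs_l),
                   origins = dplyr::bind_rows(orig_l)),
              class = "sim_reads")
  })
}

#' Simulate per-SNP allelic RNA counts and a gene expression matrix
#'
#' For every exonic SNP, sample, and tissue: read depth is
#' Poisson(`rna_depth_mean`); the reference-allele count is binomial with
#' expected fraction 0.5 for non-imprinted genes, and for imprinted genes
#' the expressed parental allele takes fraction 1 (strict) or
#' `1 - minor_fraction` (leaky). Homozygous samples express their single
#' allele. Tissues are independent replicates of the same allelic regime.
#'
#' @inheritParams make_long_reads
#' @return A list with `allelic_counts` (one row per sample x tissue x SNP)
#'   and `expression` (per-gene total counts per sample x tissue, with gene
#'   lengths attached as the `gene_lengths` attribute).
#' @export
make_allelic_counts <- function(cohort, panel, config, truth = cohort$truth) {
  validate_sim_config(config)
  with_seed(subseed(config$seed, "rna"), {
    g <- panel$genes
    snp_gene <- rep(NA_integer_, nrow(panel$snps))
    for (ch in unique(g$chrom)) {
      in_ch <- which(panel$snps$chrom == ch)
      gi <- which(g$chrom == ch)
      hit <- match_point_to_interval(panel$snps$pos[in_ch],
                                     g$exon_start[gi], g$exon_end[gi])
      snp_gene[in_ch] <- gi[hit]
    }
    keep <- which(!is.na(snp_gene))
    tissues <- paste0("tissue", seq_len(config$n_tissues))
    n <- config$n_individuals
    ne <- length(keep)
    if (ne == 0 || n == 0) {
      allelic_counts <- tibble::tibble(
        sample = character(), tissue = character(), gene_id = character(),
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), ref_count = integer(), alt_count = integer())
    } else {
      imp <- truth$imprinted_genes
      gene_ids <- g$gene_id[snp_gene[keep]]
      imp_row <- match(gene_ids, imp$gene_id)
      # long grid: snp fastest, then sample, then tissue
      snp_i <- rep(keep, times = n * config$n_tissues)
      samp_i <- rep(rep(seq_len(n), each = ne), times = config$n_tissues)
      tiss_i <- rep(seq_len(config$n_tissues), each = ne * n)
      hm <- cohort$truth$haplotypes$maternal[cbind(snp_i, samp_i)]
      hp <- cohort$truth$haplotypes$paternal[cbind(snp_i, samp_i)]
      imp_r <- rep(imp_row, times = n * config$n_tissues)
      is_imp <- !is.na(imp_r)
      expr_parent <- ifelse(is_imp, imp$expressed_parent[imp_r], NA)
      minor <- ifelse(is_imp, imp$minor_fraction[imp_r], NA)
      expr_allele <- ifelse(expr_parent == "maternal", hm, hp)
      p_ref <- rep(0.5, length(snp_i))
      hom <- hm == hp
      p_ref[hom] <- 1 - hm[hom]
      sel <- is_imp & !hom
      p_ref[sel] <- ifelse(expr_allele[sel] == 0L,
                           1 - minor[sel], minor[sel])
      depth <- stats::rpois(length(snp_i), config$rna_depth_mean)
      ref_count <- stats::rbinom(length(snp_i), depth, p_ref)
      allelic_counts <- tibble::tibble(
        sample = cohort$samples[samp_i],
        tissue = tissues[tiss_i],
        gene_id = rep(gene_ids, times = n * config$n_tissues),
        chrom = panel$snps$chrom[snp_i],
        pos = panel$snps$pos[snp_i],
        ref = panel$snps$ref[snp_i],
        alt = panel$snps$alt[snp_i],
        ref_count = ref_count,
        alt_count = depth - ref_count)
    }
    lam <- stats::rlnorm(nrow(g), meanlog = log(100), sdlog = 0.6)
    expression <- tidyr::expand_grid(
      gene_id = g$gene_id, sample = cohort$samples, tissue = tissues)
    if (nrow(expression) > 0) {
      expression$count <- stats::rpois(
        nrow(expression), rep(lam, each = n * config$n_tissues))
    } else expression$count <- integer()
    attr(expression, "gene_lengths") <-
      tibble::tibble(gene_id = g$gene_id,
                     length_bp = g$end - g$start + 1L)
    list(allelic_counts = allelic_counts, expression = expression)
  })
}

#' Simulate the germline bisulfite library series
#'
#' Emits one library summary per primordial-germ-cell (PGC) sample along a
#' postnatal time course (high methylation at birth, erased by mid pouch
#' life, re-established later), matched gonadal somatic cells, and adult
#' sperm, plus per-CpG calls over the ICR intervals for the deeply sequenced
#' libraries. Somatic cells average the two parental alleles (about 50% at
#' ICRs); sperm carries only the paternal state, so maternally methylated
#' ICRs are near 0% and paternally methylated ICRs near 100%.
#'
#' @param truth A `synthetic_truth`.
#' @param panel The matching `reference_panel`.
#' @param config The same [sim_config()].
#' @return A list with `libraries` (one row per library: CG and non-CG call
#'   counts, mapping efficiency, stage) and `region_calls` (per-CpG counts
#'   for the high-coverage libraries).
#' @export
make_germline_libraries <- function(truth, panel, config) {
  validate_sim_config(config)
  sm <- config$germline_stage_means
  if (any(sm < 0 | sm > 1))
    stop("config error: germline stage means must lie in [0, 1]")
  with_seed(subseed(config$seed, "germline"), {
    dpp <- c(7L, 13L, 14L, 16L, 18L, 20L, 22L, 25L, 30L, 40L, 50L, 60L,
             70L, 80L, 90L, 106L)
    stage <- ifelse(dpp < 10, "pre",
                    ifelse(dpp <= 16, "demethylated", "remethylated"))
    lib <- tibble::tibble(
      library_id = c(sprintf("pgc_%03ddpp", dpp),
                     sprintf("soma_%03ddpp", c(13L, 16L)), "sperm_adult"),
      cell_type = c(rep("PGC", length(dpp)), rep("soma", 2L), "sperm"),
      stage_dpp = c(dpp, 13L, 16L, NA_integer_)
    )
    mean_of <- c(sm[stage], sm["soma"], sm["soma"], sm["sperm"])
    true_mean <- pmin(pmax(mean_of + stats::rnorm(nrow(lib), 0, 0.02),
                           0.001), 0.999)
    lib$cg_total <- stats::rpois(nrow(lib), 20000)
    lib$cg_methylated <- stats::rbinom(nrow(lib), lib$cg_total, true_mean)
    lib$noncg_total <- stats::rpois(nrow(lib), 2 * 20000)
    lib$noncg_methylated <- stats::rbinom(nrow(lib), lib$noncg_total,
                                          config$noncg_level)
    lib$mapping_efficiency <- round(stats::runif(nrow(lib), 40, 70), 1)

    deep <- c("soma_013dpp", "soma_016dpp", "pgc_013dpp", "pgc_016dpp",
              "sperm_adult")
    err <- config$methylation_call_error
    calls_l <- list()
    ic <- truth$icrs
    if (nrow(ic) > 0) {
      for (lid in deep) {
        ct <- lib$cell_type[lib$library_id == lid]
        for (r in seq_len(nrow(ic))) {
          idx <- which(panel$cpgs$chrom == ic$chrom[r] &
                         panel$cpgs$pos >= ic$start[r] &
                         panel$cpgs$pos <= ic$end[r])
          if (length(idx) == 0) next
          p <- switch(ct,
            soma = (config$icr_methylated_level +
                      config$icr_unmethylated_level) / 2,
            PGC = config$pgc_icr_level,
            sperm = if (ic$methylated_parent[r] == "paternal")
              config$icr_methylated_level else config$icr_unmethylated_level)
          p <- p * (1 - err) + (1 - p) * err
          total <- stats::rpois(length(idx), 30)
          calls_l[[length(calls_l) + 1L]] <- tibble::tibble(
            library_id = lid, cell_type = ct,
            chrom = ic$chrom[r], pos = panel$cpgs$pos[idx],
            methylated = stats::rbinom(length(idx), total, p),
            total = total)
        }
      }
    }
    list(libraries = lib, region_calls = dplyr::bind_rows(calls_l))
  })
}

#' Simulate a complete synthetic cohort
#'
#' One-call wrapper assembling the reference panel, phased cohort with truth
#' set, long reads for the focal individual(s), allelic RNA counts, and the
#' germline bisulfite series.
#'
#' @param config A [sim_config()].
#' @param focal_individuals Samples to long-read sequence (default first).
#' @return An `imprint_sim` list with components `config`, `panel`,
#'   `cohort`, `reads`, `rna` and `germline`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            focal_individuals = NULL) {
  panel <- make_reference_panel(config)
  cohort <- make_cohort(panel, config)
  focal <- focal_individuals %||% cohort$samples[1]
  reads <- make_long_reads(cohort, panel, config, individuals = focal)
  rna <- make_allelic_counts(cohort, panel, config)
  germline <- make_germline_libraries(cohort$truth, panel, config)
  structure(list(config = config, panel = panel, cohort = cohort,
                 reads = reads, rna = rna, germline = germline,
                 focal_individuals = focal),
            class = "imprint_sim")
}

#' @export
print.imprint_sim <- function(x, ...) {
  cat("<imprint_sim>\n")
  cat(sprintf("  %d samples, %d SNPs, %s CpGs, %d genes, %d truth ICRs\n",
              length(x$cohort$samples), nrow(x$panel$snps),
              format(nrow(x$panel$cpgs), big.mark = ","),
              nrow(x$panel$genes), nrow(x$cohort$truth$icrs)))
  cat(sprintf("  %s long reads (%s), %s allelic-count rows, %d libraries\n",
              format(nrow(x$reads$reads), big.mark = ","),
              paste(x$focal_individuals, collapse = ", "),
              format(nrow(x$rna$allelic_counts), big.mark = ","),
              nrow(x$germline$libraries)))
  invisible(x)
}
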