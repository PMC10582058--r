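# Synthetic-cohort generator: determinism, genome layout, Mendelian
# inheritance, read and count sampling distributions, germline libraries.

test_that("panel generation is deterministic and respects empty cases", {
  cfg <- sim_config(seed = 11, n_chromosomes = 2, chrom_length = 2e5,
                    n_genes = 20, n_icrs = 2, n_individuals = 4)
  p1 <- make_reference_panel(cfg)
  p2 <- make_reference_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$genes), 20)
  expect_true(all(p1$genes$end <= cfg$chrom_length))
  # positions strictly increasing per chromosome, SNPs never on CpGs
  for (ch in p1$chromosomes$chrom) {
    cp <- p1$cpgs$pos[p1$cpgs$chrom == ch]
    sp <- p1$snps$pos[p1$snps$chrom == ch]
    expect_true(all(diff(cp) > 0))
    expect_true(all(diff(sp) > 0))
    expect_length(intersect(cp, sp), 0)
  }
  # no genes at all: CpG/SNP tracks still valid
  cfg0 <- sim_config(seed = 11, n_chromosomes = 1, chrom_length = 2e5,
                     n_genes = 0, n_icrs = 0, n_individuals = 2)
  p0 <- make_reference_panel(cfg0)
  expect_equal(nrow(p0$genes), 0)
  expect_gt(nrow(p0$cpgs), 0)
  expect_gt(nrow(p0$snps), 0)
})

test_that("background SNP count follows the Poisson density", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 1e6,
                    snp_density = 1, n_genes = 0, n_icrs = 0,
                    n_individuals = 2)
  p <- make_reference_panel(cfg)
  expect_lt(abs(nrow(p$snps) - 1000), 3 * sqrt(1000))
})

test_that("a too-small chromosome raises a sizing error naming the constraint", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 2e4,
                    n_genes = 50, n_icrs = 1, n_individuals = 2)
  expect_error(make_reference_panel(cfg), "sizing error")
})

test_that("cohort obeys Mendelian inheritance and labels ICRs correctly", {
  cfg <- small_config(21)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  tr <- co$truth
  ped <- tr$pedigree
  mat <- tr$haplotypes$maternal
  pat <- tr$haplotypes$paternal
  kids <- which(!is.na(ped$mother))
  expect_gt(length(kids), 0)
  for (i in kids) {
    m <- match(ped$mother[i], co$samples)
    # child's maternal haplotype must be one of the mother's two, per chrom
    for (ch in unique(tr$haplotypes$snps$chrom)) {
      rows <- tr$haplotypes$snps$chrom == ch
      child_mat <- mat[rows, i]
      expect_true(identical(child_mat, mat[rows, m]) ||
                    identical(child_mat, pat[rows, m]))
    }
    # mother hom => child carries that allele (Mendelian consistency)
    hom <- mat[, m] == pat[, m]
    expect_true(all(mat[hom, i] == mat[hom, m]))
  }
  # expressed parent is always opposite to the methylated parent
  joined <- merge(tr$icrs, tr$imprinted_genes, by = c("icr_id", "gene_id"))
  expect_true(all(ifelse(joined$methylated_parent == "maternal",
                         "paternal", "maternal") ==
                    joined$expressed_parent))
  # every ICR is within the discoverability distance of its gene
  g <- p$genes[match(tr$icrs$gene_id, p$genes$gene_id), ]
  expect_true(all(abs(tr$icrs$end - g$start) <= cfg$icr_gene_max_distance))
})

test_that("all ICRs are maternal when the maternal fraction is 1", {
  cfg <- small_config(3, fraction_maternal_methylated_icrs = 1)
  co <- make_cohort(make_reference_panel(cfg), cfg)
  expect_true(all(co$truth$icrs$methylated_parent == "maternal"))
})

test_that("heterozygote frequency tracks 2p(1-p) of the panel frequency", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 3e5,
                    n_genes = 10, n_icrs = 1, n_individuals = 60,
                    fraction_with_mother = 0)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  het <- co$truth$haplotypes$maternal != co$truth$haplotypes$paternal
  # pool across founder-only cohort: observed het count vs binomial CI
  expected <- sum(2 * p$snps$freq * (1 - p$snps$freq)) * 60
  observed <- sum(het)
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("error-free reads match one haplotype and cover at expected depth", {
  cfg <- small_config(13, methylation_call_error = 0, snp_read_error = 0)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  rd <- make_long_reads(co, p, cfg)
  focal <- co$samples[1]
  icol <- match(focal, co$samples)
  mat <- co$truth$haplotypes$maternal
  pat <- co$truth$haplotypes$paternal
  snp_key <- paste(co$truth$haplotypes$snps$chrom,
                   co$truth$haplotypes$snps$pos)
  origin <- rd$origins$haplotype[match(rd$read_snps$read_id,
                                       rd$origins$read_id)]
  idx <- match(paste(rd$read_snps$chrom, rd$read_snps$pos), snp_key)
  truth_allele <- ifelse(origin == "maternal", mat[cbind(idx, icol)],
                         pat[cbind(idx, icol)])
  expect_identical(rd$read_snps$allele, as.integer(truth_allele))

  # mean per-CpG depth within 3 sigma of the nominal coverage
  depth <- table(paste(rd$read_cpgs$chrom, rd$read_cpgs$pos))
  expect_lt(abs(mean(depth) - cfg$read_depth),
            3 * sqrt(cfg$read_depth))

  # maternal reads over a maternally methylated ICR are fully methylated
  mat_icr <- co$truth$icrs[co$truth$icrs$methylated_parent == "maternal", ]
  if (nrow(mat_icr) > 0) {
    r1 <- mat_icr[1, ]
    in_icr <- rd$read_cpgs$chrom == r1$chrom &
      rd$read_cpgs$pos >= r1$start & rd$read_cpgs$pos <= r1$end
    ori <- rd$origins$haplotype[match(rd$read_cpgs$read_id[in_icr],
                                      rd$origins$read_id)]
    expect_true(all(rd$read_cpgs$methylated[in_icr][ori == "maternal"] == 1))
    expect_true(all(rd$read_cpgs$methylated[in_icr][ori == "paternal"] == 0))
  }
})

test_that("reads longer than the chromosome are rejected", {
  cfg <- small_config(1)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  cfg2 <- cfg
  cfg2$read_length <- as.integer(cfg$chrom_length + 1)
  expect_error(make_long_reads(co, p, cfg2), "sizing error")
})

test_that("allelic counts follow the imprinting regime", {
  cfg <- small_config(31, rna_depth_mean = 40)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  rna <- make_allelic_counts(co, p, cfg)
  ac <- rna$allelic_counts
  tr <- co$truth
  mat <- tr$haplotypes$maternal; pat <- tr$haplotypes$paternal
  snp_key <- paste(tr$haplotypes$snps$chrom, tr$haplotypes$snps$pos)
  ridx <- match(paste(ac$chrom, ac$pos), snp_key)
  cidx <- match(ac$sample, co$samples)
  het <- mat[cbind(ridx, cidx)] != pat[cbind(ridx, cidx)]
  imp <- ac$gene_id %in% tr$imprinted_genes$gene_id
  strict <- ac$gene_id %in%
    tr$imprinted_genes$gene_id[!tr$imprinted_genes$leaky]

  # strict imprinted het rows: silenced-allele count is exactly 0
  sil <- het & strict
  expect_true(all(pmin(ac$ref_count[sil], ac$alt_count[sil]) == 0))

  # non-imprinted het rows pool to ~0.5 reference fraction
  bi <- het & !imp
  n <- sum(ac$ref_count[bi] + ac$alt_count[bi])
  frac <- sum(ac$ref_count[bi]) / n
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n))

  # leaky genes pool to the configured minor fraction
  leaky_ids <- tr$imprinted_genes$gene_id[tr$imprinted_genes$leaky]
  lk <- het & ac$gene_id %in% leaky_ids
  if (sum(lk) > 20) {
    minor <- pmin(ac$ref_count[lk], ac$alt_count[lk])
    tot <- ac$ref_count[lk] + ac$alt_count[lk]
    mf <- sum(minor) / sum(tot)
    expect_lt(abs(mf - cfg$leaky_minor_fraction),
              4 * sqrt(0.15 * 0.85 / sum(tot)) + 0.02)
  }
})

test_that("germline libraries track stage means and sperm mirrors truth", {
  cfg <- small_config(41, methylation_call_error = 0)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  gl <- make_germline_libraries(co$truth, p, cfg)
  lib <- global_methylation(gl$libraries)
  # each library's global methylation within 3 sigma of its stage mean
  sm <- cfg$germline_stage_means
  stage <- ifelse(lib$cell_type == "soma", "soma",
                  ifelse(lib$cell_type == "sperm", "sperm",
                         ifelse(lib$stage_dpp < 10, "pre",
                                ifelse(lib$stage_dpp <= 16, "demethylated",
                                       "remethylated"))))
  mu <- 100 * sm[stage]
  tol <- 3 * 100 * sqrt(0.25 / lib$cg_total) + 3 * 2  # binomial + jitter sd
  expect_true(all(abs(lib$global_methylation - mu) < tol))

  # sperm region calls agree exactly with the truth parent labels
  sperm <- gl$region_calls[gl$region_calls$cell_type == "sperm", ]
  for (r in seq_len(nrow(co$truth$icrs))) {
    icr <- co$truth$icrs[r, ]
    sel <- sperm$chrom == icr$chrom & sperm$pos >= icr$start &
      sperm$pos <= icr$end
    frac <- sum(sperm$methylated[sel]) / sum(sperm$total[sel])
    if (icr$methylated_parent == "paternal") expect_gt(frac, 0.8)
    else expect_lt(frac, 0.2)
  }
  # soma sits at the allelic average (~50%) over ICRs
  soma <- gl$region_calls[gl$region_calls$cell_type == "soma", ]
  frac <- sum(soma$methylated) / sum(soma$total)
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("stage means outside [0,1] are rejected", {
  expect_error(
    sim_config(germline_stage_means = c(pre = 1.2, demethylated = 0.4,
                                        remethylated = 0.6, sperm = 0.6,
                                        soma = 0.7)),
    "config error")
})

test_that("simulation round-trips through the plain-text writers", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chrom_length = 1e5,
                    n_genes = 10, n_icrs = 1, n_individuals = 4,
                    read_depth = 5)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "genotypes.vcf")))
  hv <- read_het_variants(file.path(dir, "genotypes.vcf"),
                          sample = sim$cohort$samples[1])
  gt <- sim$cohort$genotypes
  expect_identical(hv$pos,
                   gt$pos[gt[[sim$cohort$samples[1]]] %in%
                            c("0|1", "1|0")])
  rt <- read_reads_tsv(file.path(dir, "reads.tsv"))
  expect_equal(nrow(rt$read_snps), nrow(sim$reads$read_snps))
  expect_equal(sum(rt$read_cpgs$methylated),
               sum(sim$reads$read_cpgs$methylated))
})
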