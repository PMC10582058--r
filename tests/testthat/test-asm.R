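# ASM calling: exact per-CpG test values, depth gate, cluster thresholds,
# annotation window and tie-breaks, swap symmetry and monotonicity.

test_that("per-CpG exact test reproduces enumeration values and the depth gate", {
  counts <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    hap1_meth = c(10L, 5L, 3L), hap1_total = c(10L, 10L, 4L),
    hap2_meth = c(0L, 5L, 0L), hap2_total = c(10L, 10L, 10L))
  d <- test_cpg_differential(counts, min_depth_per_hap = 5, alpha = 0.01)
  # the (3/4 vs 0/10) CpG is skipped by the depth gate
  expect_equal(d$pos, c(100L, 200L))
  # 10/10 vs 0/10: p = 2/choose(20,10), frozen from the enumeration oracle
  expect_equal(d$p[1], 2 / 184756, tolerance = 1e-12)
  expect_equal(d$p[1], oracle_fisher_p(10, 10, 0, 10), tolerance = 1e-12)
  expect_true(d$differential[1])
  expect_equal(d$direction[1], 1L)
  # identical proportions: p = 1
  expect_equal(d$p[2], 1)
  expect_false(d$differential[2])
})

test_that("cluster size threshold is inclusive at 20 CpGs", {
  mk <- function(n) tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 50L,
    hap1_frac = 1, hap2_frac = 0, p = 1e-6, direction = 1L,
    differential = TRUE)
  expect_equal(nrow(call_asm_sites(mk(19))), 0)
  s <- call_asm_sites(mk(20))
  expect_equal(nrow(s), 1)
  expect_equal(s$n_cpg, 20L)
  expect_equal(c(s$start, s$end), c(49L, 1000L))
})

test_that("clusters split at the maximum gap and direction consistency gates sites", {
  d <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq_len(20) * 50L, 20000L + seq_len(20) * 50L),
    hap1_frac = 1, hap2_frac = 0, p = 1e-6, direction = 1L,
    differential = TRUE)
  s <- call_asm_sites(d, max_gap = 5000)
  expect_equal(nrow(s), 2)
  # flip 3 of 20 directions: consistency 17/20 < 0.9 drops that cluster
  d$direction[1:3] <- -1L
  s2 <- call_asm_sites(d, max_gap = 5000)
  expect_equal(nrow(s2), 1)
})

test_that("raising min_cpg never increases the number of sites", {
  set.seed(8)
  pos <- sort(sample.int(1e5, 400))
  d <- tibble::tibble(chrom = "chr1", pos = pos, hap1_frac = 1,
                      hap2_frac = 0, p = 1e-6, direction = 1L,
                      differential = TRUE)
  n_sites <- vapply(c(5L, 10L, 20L, 40L), function(m)
    nrow(call_asm_sites(d, min_cpg = m)), 0L)
  expect_true(all(diff(n_sites) <= 0))
})

test_that("swapping haplotype labels flips directions but not sites", {
  cfg <- small_config(19)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  rd <- make_long_reads(co, p, cfg)
  gt <- co$truth$haplotypes
  het <- tibble::tibble(chrom = gt$snps$chrom, pos = gt$snps$pos)[
    gt$maternal[, 1] != gt$paternal[, 1], ]
  blocks <- suppressMessages(phase_variants(rd$read_snps, het))
  asg <- assign_read_haplotypes(rd$read_snps, blocks)
  hmc <- haplotype_methylation_counts(rd$read_cpgs, asg)
  swapped <- dplyr::rename(hmc, hap1_meth = "hap2_meth",
                           hap1_total = "hap2_total",
                           hap2_meth = "hap1_meth",
                           hap2_total = "hap1_total")
  d1 <- test_cpg_differential(hmc)
  d2 <- test_cpg_differential(swapped)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$direction, -d2$direction)
  s1 <- call_asm_sites(d1)
  s2 <- call_asm_sites(d2)
  expect_equal(s1[, c("chrom", "start", "end", "n_cpg")],
               s2[, c("chrom", "start", "end", "n_cpg")])
  expect_equal(s1$mean_hap1, s2$mean_hap2)
})

test_that("annotation respects the window boundary and breaks ties lexicographically", {
  genes <- tibble::tibble(
    gene_id = c("gB", "gA", "gC"), chrom = "chr1",
    start = c(1000L, 61000L, 200000L), end = c(2000L, 62000L, 201000L))
  sites <- tibble::tibble(
    site_id = c("s1", "s2", "s3"), chrom = "chr1",
    start = c(1499L, 31499L, 150000L), end = c(1501L, 31501L, 150010L),
    n_cpg = 20L, mean_hap1 = 1, mean_hap2 = 0, direction = 1L)
  ann <- annotate_asm_sites(sites, genes, window = 20000)
  # inside gB: distance 0
  expect_equal(ann$gene_id[1], "gB")
  expect_equal(ann$gene_distance[1], 0)
  # equidistant (29,500 bp) from gB and gA but outside the 20 kb window
  expect_true(is.na(ann$gene_id[2]))
  # 20,001 bp beyond the window edge: unannotated
  site <- tibble::tibble(site_id = "s", chrom = "chr1",
                         start = 22000L, end = 22002L, n_cpg = 20L,
                         mean_hap1 = 1, mean_hap2 = 0, direction = 1L)
  g1 <- tibble::tibble(gene_id = "g", chrom = "chr1",
                       start = 42002L, end = 43000L)
  expect_true(is.na(annotate_asm_sites(site, g1, window = 20000)$gene_id))
  g2 <- tibble::tibble(gene_id = "g", chrom = "chr1",
                       start = 42001L, end = 43000L)
  expect_equal(annotate_asm_sites(site, g2, window = 20000)$gene_id, "g")
  # exact equidistance inside the window: lexicographically smaller id
  tie_genes <- tibble::tibble(gene_id = c("gZ", "gA"), chrom = "chr1",
                              start = c(100L, 3001L), end = c(1000L, 4000L))
  tie_site <- tibble::tibble(site_id = "s", chrom = "chr1",
                             start = 2000L, end = 2001L, n_cpg = 20L,
                             mean_hap1 = 1, mean_hap2 = 0, direction = 1L)
  expect_equal(annotate_asm_sites(tie_site, tie_genes)$gene_id, "gA")
})

test_that("ASM recall and precision are perfect on noise-free simulations", {
  hits <- 0L; truth_n <- 0L; called_n <- 0L; correct <- 0L
  for (seed in 1:5) {
    cfg <- small_config(seed, methylation_call_error = 0,
                        snp_read_error = 0)
    p <- make_reference_panel(cfg)
    co <- make_cohort(p, cfg)
    rd <- make_long_reads(co, p, cfg)
    gt <- co$truth$haplotypes
    het <- tibble::tibble(chrom = gt$snps$chrom, pos = gt$snps$pos)[
      gt$maternal[, 1] != gt$paternal[, 1], ]
    blocks <- suppressMessages(phase_variants(rd$read_snps, het))
    asg <- assign_read_haplotypes(rd$read_snps, blocks)
    hmc <- haplotype_methylation_counts(rd$read_cpgs, asg)
    sites <- call_asm_sites(test_cpg_differential(hmc))
    icrs <- co$truth$icrs
    truth_n <- truth_n + nrow(icrs)
    called_n <- called_n + nrow(sites)
    for (r in seq_len(nrow(icrs))) {
      ov <- sites$chrom == icrs$chrom[r] & sites$start < icrs$end[r] &
        sites$end > icrs$start[r]
      if (any(ov)) hits <- hits + 1L
      correct <- correct + sum(ov)
    }
  }
  expect_equal(hits, truth_n)     # full recall
  expect_equal(correct, called_n) # no false sites
})
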