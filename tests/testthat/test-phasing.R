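# Phasing: MEC optimality against the exhaustive oracle, block structure,
# assignment rules and tallying identities.

test_that("consistent error-free reads recover the true phasing", {
  set.seed(1)
  truth <- c(0L, 1L, 1L)
  reads <- lapply(1:10, function(r) {
    hap <- r %% 2L
    tibble::tibble(read_id = sprintf("r%02d", r), chrom = "chr1",
                   pos = c(100L, 200L, 300L),
                   allele = if (hap == 0L) truth else 1L - truth)
  })
  rs <- dplyr::bind_rows(reads)
  het <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L))
  blocks <- phase_variants(rs, het)
  expect_equal(length(unique(blocks$block_id)), 1)
  # canonical: hap1 has ref at first SNP; partition matches truth up to swap
  expect_equal(blocks$hap1_allele, truth)  # truth[1] == 0 so no swap
  # greedy result achieves the exhaustive MEC optimum
  amat <- matrix(rep(c(truth, 1L - truth), 5), ncol = 3, byrow = TRUE)
  expect_equal(mec_cost_of(amat, blocks$hap1_allele), oracle_mec_cost(amat))
})

test_that("SNPs never co-covered fall into singleton blocks", {
  rs <- tibble::tibble(read_id = c("a", "b"), chrom = "chr1",
                       pos = c(100L, 900L), allele = c(0L, 1L))
  het <- tibble::tibble(chrom = "chr1", pos = c(100L, 900L))
  blocks <- phase_variants(rs, het)
  expect_equal(length(unique(blocks$block_id)), 2)
  expect_true(all(blocks$hap1_allele == 0L))  # canonical per block
})

test_that("empty het set gives an empty block list, unknown positions are counted", {
  rs <- tibble::tibble(read_id = "a", chrom = "chr1", pos = 5L, allele = 1L)
  expect_equal(nrow(phase_variants(
    rs, tibble::tibble(chrom = character(), pos = integer()))), 0)
  het <- tibble::tibble(chrom = "chr1", pos = 100L)
  expect_message(b <- phase_variants(
    dplyr::bind_rows(rs, tibble::tibble(read_id = c("a", "b"),
                                        chrom = "chr1", pos = 100L,
                                        allele = c(0L, 0L))),
    het), "ignored 1")
  expect_equal(attr(b, "n_ignored"), 1L)
})

test_that("greedy phasing equals exhaustive MEC on random small blocks", {
  set.seed(42)
  n_opt <- 0L
  n_cases <- 60L
  for (k in seq_len(n_cases)) {
    nsnp <- sample(3:10, 1)
    inst <- simulate_phasing_instance(nsnp, depth = 8, error = 0.05)
    blocks <- suppressMessages(phase_variants(inst$read_snps, inst$het,
                                              min_link_reads = 1L))
    # evaluate only fully linked instances (single block)
    if (length(unique(blocks$block_id)) != 1L) next
    got <- mec_cost_of(inst$amat, blocks$hap1_allele)
    opt <- oracle_mec_cost(inst$amat)
    expect_gte(got, opt)
    if (got == opt) n_opt <- n_opt + 1L
    expect_equal(got, opt)
  }
  expect_gt(n_opt, 0)
})

test_that("switch errors are absent at realistic depth and error rate", {
  set.seed(7)
  switches <- 0L
  for (k in 1:100) {
    nsnp <- sample(4:10, 1)
    inst <- simulate_phasing_instance(nsnp, depth = 30, error = 0.01)
    blocks <- suppressMessages(phase_variants(inst$read_snps, inst$het))
    for (b in unique(blocks$block_id)) {
      sel <- blocks$block_id == b
      idx <- match(blocks$pos[sel], inst$het$pos)
      rel_called <- diff(blocks$hap1_allele[sel])
      rel_truth <- diff(inst$truth[idx])
      switches <- switches + sum(abs(rel_called) != abs(rel_truth))
    }
  }
  expect_equal(switches, 0L)
})

test_that("read assignment follows majority vote with deterministic tie rules", {
  blocks <- tibble::tibble(block_id = "b1", chrom = "chr1",
                           pos = c(1L, 2L, 3L, 4L) * 100L,
                           hap1_allele = c(0L, 0L, 1L, 1L),
                           hap2_allele = c(1L, 1L, 0L, 0L),
                           n_reads = 5L)
  rs <- tibble::tibble(
    read_id = c(rep("maj", 4), rep("tie", 2)),
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 100L, 300L),
    allele = c(0L, 0L, 1L, 0L,   0L, 0L))
  asg <- assign_read_haplotypes(rs, blocks, read_ids = c("maj", "tie", "none"))
  maj <- asg[asg$read_id == "maj", ]
  expect_equal(maj$haplotype, 1L)
  expect_equal(c(maj$votes_hap1, maj$votes_hap2), c(3L, 1L))
  expect_true(is.na(asg$haplotype[asg$read_id == "tie"]))  # 1-1 votes
  expect_true(is.na(asg$haplotype[asg$read_id == "none"]))
})

test_that("reads spanning two blocks vote in the more informative block only", {
  blocks <- tibble::tibble(
    block_id = c("b1", "b1", "b2"), chrom = "chr1",
    pos = c(100L, 200L, 900L),
    hap1_allele = c(0L, 0L, 0L), hap2_allele = c(1L, 1L, 1L),
    n_reads = 5L)
  rs <- tibble::tibble(read_id = "x", chrom = "chr1",
                       pos = c(100L, 200L, 900L), allele = c(1L, 1L, 0L))
  asg <- assign_read_haplotypes(rs, blocks)
  expect_equal(asg$block_id, "b1")
  expect_equal(asg$haplotype, 2L)
})

test_that("error-free simulator reads are all assigned to their true haplotype", {
  cfg <- small_config(17, methylation_call_error = 0, snp_read_error = 0)
  p <- make_reference_panel(cfg)
  co <- make_cohort(p, cfg)
  rd <- make_long_reads(co, p, cfg)
  focal <- co$samples[1]
  gt <- co$truth$haplotypes
  het <- tibble::tibble(
    chrom = gt$snps$chrom, pos = gt$snps$pos
  )[gt$maternal[, 1] != gt$paternal[, 1], ]
  blocks <- suppressMessages(phase_variants(rd$read_snps, het))
  asg <- assign_read_haplotypes(rd$read_snps, blocks)
  asg <- asg[!is.na(asg$haplotype), ]
  ori <- rd$origins$haplotype[match(asg$read_id, rd$origins$read_id)]
  # within each block the hap1/hap2 <-> parental mapping is consistent
  tab <- table(asg$block_id, asg$haplotype, ori)
  for (b in dimnames(tab)[[1]]) {
    m <- tab[b, , ]
    # each called haplotype maps to exactly one parent
    expect_true(all(apply(m, 1, function(x) min(x) == 0)))
  }
})

test_that("haplotype methylation tallies satisfy the accounting identity", {
  asg <- tibble::tibble(read_id = c("a", "b", "c"), block_id = "b1",
                        haplotype = c(1L, 2L, NA), votes_hap1 = 1L,
                        votes_hap2 = 0L)
  rc <- tibble::tibble(
    read_id = rep(c("a", "b", "c"), each = 2),
    chrom = "chr1", pos = rep(c(10L, 20L), 3),
    methylated = c(1L, 1L, 0L, 0L, 1L, 1L))
  tallies <- haplotype_methylation_counts(rc, asg)
  expect_equal(nrow(tallies), 2)
  expect_equal(tallies$hap1_meth, c(1L, 1L))
  expect_equal(tallies$hap2_total, c(1L, 1L))
  # grand total = assigned reads x covered CpGs
  expect_equal(sum(tallies$hap1_total + tallies$hap2_total), 4)
  # all reads unassigned -> empty table
  asg$haplotype <- NA_integer_
  expect_equal(nrow(haplotype_methylation_counts(rc, asg)), 0)
})
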