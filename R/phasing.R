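# Read-backed phasing of heterozygous SNPs and haplotype assignment of
# methylation-bearing long reads. No randomness anywhere in this module.

#' Phase heterozygous SNPs from long-read allele observations
#'
#' Greedy left-to-right minimum-error-correction (MEC) phasing. Adjacent
#' heterozygous SNPs co-covered by at least `min_link_reads` reads fall in
#' one phase block; within a block each new SNP is oriented by majority vote
#' of the reads linking it to the already-phased prefix, followed by a
#' coordinate-descent refinement (reassign reads to their closer haplotype,
#' re-orient each SNP by majority) until the MEC cost stops improving.
#' Haplotype labels are canonicalised so hap1 carries the reference allele at
#' the first SNP of each block; parental identity is *not* claimed here.
#'
#' @param read_snps Tibble of per-read allele observations: `read_id`,
#'   `chrom`, `pos`, `allele` (0 = ref, 1 = alt).
#' @param het_variants Tibble of heterozygous sites for the focal
#'   individual: `chrom`, `pos` (plus any allele columns, carried through).
#'   Observations at positions absent from `het_variants` are ignored; their
#'   count is reported via a message and the `n_ignored` attribute.
#' @param min_link_reads Minimum reads co-covering two adjacent SNPs for
#'   them to share a block (default 2; single-read linkage is too
#'   error-prone at realistic error rates).
#' @return Tibble with one row per phased SNP: `block_id`, `chrom`, `pos`,
#'   `hap1_allele`, `hap2_allele` (complementary), `n_reads` support.
#' @export
phase_variants <- function(read_snps, het_variants, min_link_reads = 2L) {
  empty <- tibble::tibble(block_id = character(), chrom = character(),
                          pos = integer(), hap1_allele = integer(),
                          hap2_allele = integer(), n_reads = integer())
  if (nrow(het_variants) == 0L) return(empty)
  het_key <- paste(het_variants$chrom, het_variants$pos)
  obs_key <- paste(read_snps$chrom, read_snps$pos)
  known <- obs_key %in% het_key
  n_ignored <- sum(!known)
  if (n_ignored > 0)
    rlang::inform(sprintf(
      "phase_variants: ignored %d observation(s) at positions absent from het_variants",
      n_ignored))
  obs <- dplyr::distinct(read_snps[known, ],
                         .data$read_id, .data$chrom, .data$pos,
                         .keep_all = TRUE)

  out <- list()
  block_n <- 0L
  for (ch in unique(het_variants$chrom)) {
    hv <- het_variants[het_variants$chrom == ch, ]
    hv <- hv[order(hv$pos), ]
    nsnp <- nrow(hv)
    if (nsnp == 0L) next
    o <- obs[obs$chrom == ch, ]
    snp_of <- match(o$pos, hv$pos)
    read_of <- as.integer(factor(o$read_id))
    # reads co-covering each consecutive SNP pair, and their allele parity
    ord <- order(read_of, snp_of)
    rr <- read_of[ord]; ss <- snp_of[ord]; aa <- o$allele[ord]
    m <- length(rr)
    link <- integer(max(nsnp - 1L, 0L))
    xorv <- integer(max(nsnp - 1L, 0L))
    if (m > 1L && nsnp > 1L) {
      adj <- rr[-1] == rr[-m] & ss[-1] == ss[-m] + 1L
      link <- tabulate(ss[-m][adj], nbins = nsnp - 1L)
      xorv <- tabulate(ss[-m][adj & aa[-1] != aa[-m]], nbins = nsnp - 1L)
    }
    # greedy left-to-right: orient each SNP against its left neighbour by
    # majority linkage (ties keep the same orientation)
    flip <- if (nsnp > 1L) as.integer(2L * xorv > link) else integer()
    rel_phase <- cumsum(c(0L, flip)) %% 2L
    brk <- c(0L, if (nsnp > 1L) which(link < min_link_reads), nsnp)
    for (b in seq_len(length(brk) - 1L)) {
      idx <- (brk[b] + 1L):brk[b + 1L]
      block_n <- block_n + 1L
      sel <- which(snp_of %in% idx)
      s_loc <- snp_of[sel] - idx[1L] + 1L
      r_loc <- as.integer(factor(read_of[sel]))
      init <- (rel_phase[idx] + rel_phase[idx[1L]]) %% 2L
      phase <- phase_block_mec(r_loc, s_loc, o$allele[sel], length(idx),
                               init = init)
      if (length(phase) && phase[1L] == 1L) phase <- 1L - phase  # canonical
      out[[length(out) + 1L]] <- tibble::tibble(
        block_id = sprintf("%s_b%04d", ch, block_n),
        chrom = ch, pos = hv$pos[idx],
        hap1_allele = phase, hap2_allele = 1L - phase,
        n_reads = tabulate(s_loc, nbins = length(idx)))
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else empty
  attr(res, "n_ignored") <- n_ignored
  res
}

# Coordinate-descent MEC refinement of one block, on triplets
# (read index, snp index, allele), starting from the greedy orientation.
# Returns the hap1 allele vector (0/1 per SNP).
phase_block_mec <- function(read_idx, snp_idx, allele, nsnp,
                            init = integer(nsnp)) {
  phase <- as.integer(init)
  if (nsnp <= 1L || length(allele) == 0L) return(phase)
  # coordinate descent on the MEC objective
  cost_parts <- function(ph) {
    mism <- (allele != ph[snp_idx]) * 1L
    d1 <- rowsum(mism, read_idx)
    d2 <- rowsum(1L - mism, read_idx)
    list(d1 = d1[, 1L], d2 = d2[, 1L])
  }
  cp <- cost_parts(phase)
  cost <- sum(pmin(cp$d1, cp$d2))
  for (it in seq_len(50L)) {
    side1 <- cp$d1 <= cp$d2  # ties to hap1 (deterministic)
    side1_obs <- side1[match(read_idx, as.integer(names(side1)))]
    contrib <- ifelse(side1_obs, allele, 1L - allele)
    ones <- rowsum(contrib, snp_idx)
    tot <- rowsum(rep(1L, length(contrib)), snp_idx)
    new_phase <- phase
    grp <- as.integer(rownames(ones))
    new_phase[grp] <- as.integer(ones[, 1L] > tot[, 1L] - ones[, 1L])
    ncp <- cost_parts(new_phase)
    new_cost <- sum(pmin(ncp$d1, ncp$d2))
    if (new_cost < cost) {
      phase <- new_phase; cp <- ncp; cost <- new_cost
    } else break
  }
  # switch-move refinement: flipping the suffix at one position escapes the
  # local optima coordinate descent leaves behind (switch errors). Scanned
  # only on modest blocks; long blocks at realistic depth do not need it.
  if (nsnp <= 300L) {
    repeat {
      improved <- FALSE
      for (j in 2L:nsnp) {
        cand <- phase
        cand[j:nsnp] <- 1L - cand[j:nsnp]
        ccp <- cost_parts(cand)
        ccost <- sum(pmin(ccp$d1, ccp$d2))
        if (ccost < cost) {
          phase <- cand; cost <- ccost; improved <- TRUE
        }
      }
      if (!improved) break
      # re-run coordinate descent from the switched configuration
      repeat {
        cp <- cost_parts(phase)
        side1 <- cp$d1 <= cp$d2
        side1_obs <- side1[match(read_idx, as.integer(names(side1)))]
        contrib <- ifelse(side1_obs, allele, 1L - allele)
        ones <- rowsum(contrib, snp_idx)
        tot <- rowsum(rep(1L, length(contrib)), snp_idx)
        new_phase <- phase
        grp <- as.integer(rownames(ones))
        new_phase[grp] <- as.integer(ones[, 1L] > tot[, 1L] - ones[, 1L])
        ncp <- cost_parts(new_phase)
        new_cost <- sum(pmin(ncp$d1, ncp$d2))
        if (new_cost < cost) {
          phase <- new_phase; cost <- new_cost
        } else break
      }
    }
  }
  phase
}

# names() on rowsum results are rownames; keep a helper for clarity
# (rowsum returns a matrix whose rownames are the sorted group labels)

#' Assign reads to haplotypes by majority vote over phased SNPs
#'
#' Each read votes with its allele at every phased SNP it covers. Reads
#' spanning two blocks vote only within the block where they cover more
#' informative SNPs (block tie: unassigned). A votes tie, or zero
#' informative SNPs, leaves the read unassigned.
#'
#' @param read_snps Per-read allele observations (`read_id`, `chrom`, `pos`,
#'   `allele`).
#' @param blocks Output of [phase_variants()].
#' @param read_ids Optional vector of all read ids, so reads overlapping no
#'   phased SNP still appear as unassigned rows.
#' @return Tibble: `read_id`, `block_id` (NA if none), `haplotype`
#'   (1, 2, or NA = unassigned), `votes_hap1`, `votes_hap2`.
#' @export
assign_read_haplotypes <- function(read_snps, blocks, read_ids = NULL) {
  empty <- tibble::tibble(read_id = character(), block_id = character(),
                          haplotype = integer(), votes_hap1 = integer(),
                          votes_hap2 = integer())
  joined <- dplyr::inner_join(read_snps, blocks, by = c("chrom", "pos"))
  res <- if (nrow(joined) == 0L) empty else {
    per_block <- joined |>
      dplyr::group_by(.data$read_id, .data$block_id) |>
      dplyr::summarise(
        votes_hap1 = sum(.data$allele == .data$hap1_allele),
        votes_hap2 = sum(.data$allele == .data$hap2_allele),
        n_info = dplyr::n(), .groups = "drop")
    pb <- dplyr::arrange(per_block, .data$read_id, dplyr::desc(.data$n_info))
    n <- nrow(pb)
    first <- !duplicated(pb$read_id)
    # block tie: next row is the same read with equal informative count
    tie_next <- c(pb$read_id[-1] == pb$read_id[-n] &
                    pb$n_info[-1] == pb$n_info[-n], FALSE)
    top <- pb[first, ]
    block_tied <- tie_next[first]
    hap <- ifelse(top$votes_hap1 > top$votes_hap2, 1L,
                  ifelse(top$votes_hap2 > top$votes_hap1, 2L, NA_integer_))
    hap[block_tied] <- NA_integer_
    tibble::tibble(
      read_id = top$read_id,
      block_id = ifelse(block_tied, NA_character_, top$block_id),
      haplotype = as.integer(hap),
      votes_hap1 = ifelse(block_tied, 0L, as.integer(top$votes_hap1)),
      votes_hap2 = ifelse(block_tied, 0L, as.integer(top$votes_hap2)))
  }
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, res$read_id)
    if (length(missing) > 0L)
      res <- dplyr::bind_rows(res, tibble::tibble(
        read_id = missing, block_id = NA_character_,
        haplotype = NA_integer_, votes_hap1 = 0L, votes_hap2 = 0L))
  }
  dplyr::arrange(res, .data$read_id)
}

#' Tally per-CpG methylation by haplotype
#'
#' Unassigned reads are excluded; CpGs covered by neither haplotype are
#' omitted. Haplotype labels are only meaningful within one phase block, so
#' each CpG is tallied within a single block: when reads from two blocks
#' cover the same CpG (a phase-block boundary), only the block contributing
#' more reads there is used.
#'
#' @param read_cpgs Per-read CpG states (`read_id`, `chrom`, `pos`,
#'   `methylated` 0/1).
#' @param assignments Output of [assign_read_haplotypes()].
#' @return Tibble: `chrom`, `pos`, `hap1_meth`, `hap1_total`, `hap2_meth`,
#'   `hap2_total`.
#' @export
haplotype_methylation_counts <- function(read_cpgs, assignments) {
  asg <- assignments[!is.na(assignments$haplotype),
                     c("read_id", "block_id", "haplotype")]
  joined <- dplyr::inner_join(read_cpgs, asg, by = "read_id")
  if (nrow(joined) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          block_id = character(),
                          hap1_meth = integer(), hap1_total = integer(),
                          hap2_meth = integer(), hap2_total = integer()))
  }
  per_block <- joined |>
    dplyr::group_by(.data$chrom, .data$pos, .data$block_id) |>
    dplyr::summarise(
      hap1_meth = sum(.data$methylated[.data$haplotype == 1L]),
      hap1_total = sum(.data$haplotype == 1L),
      hap2_meth = sum(.data$methylated[.data$haplotype == 2L]),
      hap2_total = sum(.data$haplotype == 2L),
      .groups = "drop")
  per_block <- dplyr::arrange(
    per_block, .data$chrom, .data$pos,
    dplyr::desc(.data$hap1_total + .data$hap2_total), .data$block_id)
  per_block[!duplicated(per_block[, c("chrom", "pos")]), ]
}
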