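# Independent oracles used to freeze expected values. Each is deliberately
# implemented by a different route than the package code it checks.

# Two-sided Fisher exact p by explicit log-factorial enumeration of the
# conditioned 2x2 tables (no dhyper, no fisher.test).
oracle_fisher_p <- function(x1, n1, x2, n2) {
  s <- x1 + x2
  N <- n1 + n2
  lo <- max(0, s - n2)
  hi <- min(s, n1)
  logprob <- function(k) {
    lchoose(n1, k) + lchoose(n2, s - k) - lchoose(N, s)
  }
  lp <- vapply(lo:hi, logprob, numeric(1))
  p <- exp(lp)
  sum(p[p <= p[x1 - lo + 1] * (1 + 1e-7)])
}

# Exact HWE heterozygote-deficiency p by sequential random pairing of the
# allele pool (hypergeometric recursion over genotype draws), an
# independent derivation from the closed multinomial formula.
oracle_hwe_p <- function(n_AA, n_AB, n_BB) {
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  memo <- new.env(hash = TRUE)
  # P(total hets = h) building individuals one at a time
  dist <- function(a, b) {
    key <- paste(a, b)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- a + b
    if (tot == 0) return(c(`0` = 1))
    pairs <- choose(tot, 2)
    res <- numeric(0)
    add <- function(res, h, p) {
      k <- as.character(h)
      res[k] <- (if (is.na(res[k])) 0 else res[k]) + p
      res
    }
    if (a >= 2) {
      sub <- dist(a - 2, b)
      for (h in names(sub))
        res <- add(res, as.integer(h), choose(a, 2) / pairs * sub[[h]])
    }
    if (b >= 2) {
      sub <- dist(a, b - 2)
      for (h in names(sub))
        res <- add(res, as.integer(h), choose(b, 2) / pairs * sub[[h]])
    }
    if (a >= 1 && b >= 1) {
      sub <- dist(a - 1, b - 1)
      for (h in names(sub))
        res <- add(res, as.integer(h) + 1L, a * b / pairs * sub[[h]])
    }
    memo[[key]] <- res
    res
  }
  d <- dist(nA, nB)
  sum(d[as.integer(names(d)) <= n_AB])
}

# Exact minimum-error-correction phasing cost by exhausting all 2^(n-1)
# orientations of a block (first SNP fixed to 0).
oracle_mec_cost <- function(amat) {
  nsnp <- ncol(amat)
  best <- Inf
  for (code in 0:(2^(nsnp - 1) - 1)) {
    phase <- c(0L, as.integer(intToBits(code))[seq_len(nsnp - 1)])
    mm1 <- rowSums(sweep(amat, 2, phase, `!=`), na.rm = TRUE)
    mm2 <- rowSums(sweep(amat, 2, 1L - phase, `!=`), na.rm = TRUE)
    best <- min(best, sum(pmin(mm1, mm2)))
  }
  best
}

# MEC cost of a given phasing on an observation matrix
mec_cost_of <- function(amat, phase) {
  mm1 <- rowSums(sweep(amat, 2, phase, `!=`), na.rm = TRUE)
  mm2 <- rowSums(sweep(amat, 2, 1L - phase, `!=`), na.rm = TRUE)
  sum(pmin(mm1, mm2))
}

# Simulate a small phasing instance: reads of `span` adjacent SNPs from two
# complementary haplotypes with allele flip errors. Returns observation
# matrix plus the tidy read_snps/het tables the package functions take.
simulate_phasing_instance <- function(nsnp, depth, error, span = 4L) {
  truth <- rbinom(nsnp, 1L, 0.5)
  rows <- list()
  reads <- max(2L, round(depth * nsnp / span))
  for (r in seq_len(reads)) {
    s0 <- sample.int(max(nsnp - span + 1L, 1L), 1L)
    idx <- s0:min(s0 + span - 1L, nsnp)
    hap <- sample(c(0L, 1L), 1L)
    base <- if (hap == 0L) truth[idx] else 1L - truth[idx]
    obs <- (base + rbinom(length(idx), 1L, error)) %% 2L
    rows[[r]] <- data.frame(read_id = sprintf("r%03d", r), chrom = "chr1",
                            pos = idx * 100L, allele = obs)
  }
  obs_df <- do.call(rbind, rows)
  amat <- matrix(NA_integer_, reads, nsnp)
  amat[cbind(match(obs_df$read_id, sprintf("r%03d", seq_len(reads))),
             obs_df$pos / 100L)] <- obs_df$allele
  list(truth = truth,
       read_snps = tibble::as_tibble(obs_df),
       het = tibble::tibble(chrom = "chr1", pos = (1:nsnp) * 100L),
       amat = amat)
}

# small default config for fast whole-pipeline tests
small_config <- function(seed, ...) {
  args <- list(seed = seed, n_chromosomes = 1L, chrom_length = 4e5,
               n_genes = 60L, n_icrs = 3L, n_individuals = 12L,
               fraction_with_mother = 0.5, read_depth = 25)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
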