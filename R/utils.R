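# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a labelled sub-seed from a master seed
#'
#' Deterministic 31-bit hash of `(seed, label)`. Each simulator output draws
#' from its own stream so that adding one output never perturbs the others.
#'
#' @param seed Master integer seed.
#' @param label Character label naming the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
subseed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Two-sided Fisher exact p for 2x2 tables of successes/totals
#'
#' Conditional hypergeometric test that group-1 and group-2 success
#' probabilities are equal, given `x1/n1` and `x2/n2` successes/totals.
#' Vectorised; duplicate margin configurations are computed once, which makes
#' genome-scale per-CpG and per-SNP screens fast.
#'
#' @param x1,n1 Successes and totals in group 1.
#' @param x2,n2 Successes and totals in group 2.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher2x2_p(10, 10, 0, 10)  # 2 / choose(20, 10)
#' @export
fisher2x2_p <- function(x1, n1, x2, n2) {
  m <- cbind(x1, n1, x2, n2)
  stopifnot(all(m >= 0), all(x1 <= n1), all(x2 <= n2))
  key <- paste(m[, 1], m[, 2], m[, 3], m[, 4])
  uniq <- !duplicated(key)
  one <- function(a, na, b, nb) {
    s <- a + b
    lo <- max(0L, s - nb)
    hi <- min(s, na)
    d <- stats::dhyper(lo:hi, s, na + nb - s, na)
    sum(d[d <= d[a - lo + 1L] * (1 + 1e-7)])
  }
  pu <- mapply(one, m[uniq, 1], m[uniq, 2], m[uniq, 3], m[uniq, 4])
  unname(pu[match(key, key[uniq])])
}

# 1-based closed interval overlap between a point vector and intervals,
# returning the interval index for each point (NA_integer_ when none; first
# interval wins on overlap ties). Intervals must not be needed to overlap.
match_point_to_interval <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(NA_integer_, length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = pos, width = 1L),
    IRanges::IRanges(start = starts, end = ends),
    select = "first"
  )
  as.integer(hits)
}
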