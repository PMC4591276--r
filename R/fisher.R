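#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Computes the exact two-sided p-value for the 2x2 table
#' `[[a, b], [c, d]]` — in this package's use, `[[ref_s, alt_s],
#' [ref_r, alt_r]]` for one variant in the sensitive and resistant samples.
#' The two-sided p-value sums, over all tables with the observed margins, the
#' hypergeometric probabilities that do not exceed the probability of the
#' observed table (tables tied with the observed one are included using a
#' relative tolerance of 1e-7, the convention of [stats::fisher.test()]).
#' When either margin is degenerate (an all-zero row or column) only one
#' table is possible and the p-value is 1.
#'
#' All four arguments are vectorized and recycled to a common length.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_two_sided(1, 1, 1, 1)      # 1: the symmetric table
#' fisher_exact_two_sided(10, 0, 0, 10)    # 2/choose(20, 10)
#' fisher_exact_two_sided(100, 0, 65, 35)  # de-novo variant at depth 100
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (anyNA(cells)) abort("cell counts must not be NA")
  if (any(cells < 0)) abort("cell counts must be non-negative")
  if (any(cells != floor(cells))) abort("cell counts must be integers")
  vapply(seq_len(n), function(i) {
    fisher_p_one(a[i], b[i], c[i], d[i])
  }, numeric(1))
}

# One table; margins (r1, r2) rows, (c1, c2) cols; x = top-left cell.
fisher_p_one <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  obs <- probs[match(a, support)]
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(p, 1)
}
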