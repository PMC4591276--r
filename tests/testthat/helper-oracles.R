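# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths (and where possible the
# distribution functions) used by the package implementation.

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, probabilities from factorial ratios via choose().
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up written as the literal procedure: sort, scale
# by n/rank, enforce monotonicity from the largest p down, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, scaled[i])
    adj[i] <- running
  }
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided exact binomial p by summing exp(log) outcome probabilities
# computed from lchoose, independently of dbinom.
oracle_binom_enum <- function(k, n, prob) {
  if (n == 0) return(1)
  xs <- 0:n
  lp <- lchoose(n, xs) + xs * log(prob) + (n - xs) * log(1 - prob)
  probs <- exp(lp)
  obs <- probs[k + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Overlap detection by brute force: test every candidate length
# explicitly and keep the largest acceptable one.
oracle_overlap <- function(seq1, seq2, min_overlap, max_mismatch_rate) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                          collapse = "")
  s1 <- strsplit(seq1, "")[[1]]
  s2 <- strsplit(rc(seq2), "")[[1]]
  best <- NA_integer_
  for (len in min_overlap:min(length(s1), length(s2))) {
    a <- s1[(length(s1) - len + 1):length(s1)]
    b <- s2[1:len]
    mism <- sum(a != b | a == "N" | b == "N")
    if (mism / len <= max_mismatch_rate) best <- len
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Minimal single-sample VCF text with AD genotype fields.
write_fixture_vcf <- function(path, rows, sample = "S1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- vapply(rows, function(r) {
    paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT:AD",
          paste0(r$gt, ":", r$ad), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
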