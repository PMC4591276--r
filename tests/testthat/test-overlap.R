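pair_from_fragment <- function(frag, read_length = 101) {
  len <- nchar(frag)
  list(
    seq1 = substr(frag, 1, read_length),
    seq2 = clonsel:::revcomp(substr(frag, len - read_length + 1, len))
  )
}

test_that("overlap detection recovers the fragment geometry", {
  set.seed(51)
  # long fragment: mates disjoint, no overlap
  p <- pair_from_fragment(random_dna(300))
  expect_true(is.na(detect_overlap(p$seq1, p$seq2)))
  # 150 bp fragment at 2 x 101: overlap 2*101 - 150 = 52
  p <- pair_from_fragment(random_dna(150))
  expect_equal(detect_overlap(p$seq1, p$seq2), 52L)
  # full overlap when the fragment equals the read length
  p <- pair_from_fragment(random_dna(101))
  expect_equal(detect_overlap(p$seq1, p$seq2), 101L)
})

test_that("mismatch tolerance follows the configured rate", {
  set.seed(52)
  frag <- random_dna(150)
  p <- pair_from_fragment(frag)
  # plant 2 mismatches inside the 52-base overlap: positions 82 and 97 of
  # the stored R2 map to positions 20 and 5 of its reverse complement
  s2 <- strsplit(p$seq2, "")[[1]]
  for (i in c(82, 97)) s2[i] <- setdiff(c("A", "C", "G", "T"), s2[i])[1]
  seq2_mut <- paste(s2, collapse = "")
  # 2/52 < 0.05: still detected, and the brute-force scan agrees
  expect_equal(detect_overlap(p$seq1, seq2_mut, max_mismatch_rate = 0.05), 52L)
  expect_equal(oracle_overlap(p$seq1, seq2_mut, 10, 0.05), 52L)
  # zero tolerance rejects the planted mismatches
  expect_true(is.na(detect_overlap(p$seq1, seq2_mut, max_mismatch_rate = 0)) ||
                detect_overlap(p$seq1, seq2_mut, max_mismatch_rate = 0) < 52)
})

test_that("detection matches the brute-force scan on random pairs", {
  set.seed(53)
  for (i in 1:30) {
    len <- sample(101:260, 1)
    frag <- random_dna(len)
    p <- pair_from_fragment(frag)
    expect_identical(detect_overlap(p$seq1, p$seq2, 10, 0.1),
                     oracle_overlap(p$seq1, p$seq2, 10, 0.1))
  }
})

test_that("N bases never match", {
  p <- pair_from_fragment(random_dna(150))
  s1 <- p$seq1
  substr(s1, 60, 101) <- paste(rep("N", 42), collapse = "")
  expect_true(is.na(detect_overlap(s1, p$seq2, max_mismatch_rate = 0.1)))
})

test_that("merge-and-split reconstructs the fragment exactly once", {
  sim <- simulate_read_pairs(fragment_lengths = c(150, 120, 101, 190),
                             read_length = 101, seed = 3)
  res <- merge_read_pairs(sim$pairs)
  expect_true(all(res$merged))
  expect_equal(res$overlap_len, sim$truth$overlap_len)
  # merged fragment equals the simulated truth, split covers it exactly once
  expect_equal(res$fragment_seq, sim$truth$fragment_seq)
  reassembled <- paste0(res$out_seq1, clonsel:::revcomp(res$out_seq2))
  expect_equal(reassembled, sim$truth$fragment_seq)
  lens <- nchar(res$fragment_seq)
  expect_equal(nchar(res$out_seq1), floor(lens / 2))
  expect_equal(nchar(res$out_seq2), lens - floor(lens / 2))
})

test_that("non-overlapping pairs pass through byte-identically", {
  sim <- simulate_read_pairs(fragment_lengths = c(300, 250), read_length = 101,
                             seed = 4)
  res <- merge_read_pairs(sim$pairs)
  expect_false(any(res$merged))
  expect_identical(res$out_seq1, sim$pairs$seq1)
  expect_identical(res$out_qual1, sim$pairs$qual1)
  expect_identical(res$out_seq2, sim$pairs$seq2)
  expect_identical(res$out_qual2, sim$pairs$qual2)
})

test_that("the higher-quality mate wins disagreements in the overlap", {
  # fragment of 12, reads of 8 -> overlap 4
  frag <- "ACGTACGTACGT"
  r1 <- substr(frag, 1, 8)
  r2 <- clonsel:::revcomp(substr(frag, 5, 12))
  # disagree at fragment position 6 (R1 index 6, overlap index 2)
  r1_bad <- r1; substr(r1_bad, 6, 6) <- "T"
  q_low <- paste(rep("#", 8), collapse = "")   # phred 2
  q_high <- paste(rep("I", 8), collapse = "")  # phred 40
  out <- merge_and_split(r1_bad, q_low, r2, q_high, 4)
  expect_equal(out$seq, frag)  # R2's correct base prevailed
  # tie goes to R1
  out_tie <- merge_and_split(r1_bad, q_high, r2, q_high, 4)
  expect_equal(substr(out_tie$seq, 6, 6), "T")
})

test_that("merge validates its inputs", {
  expect_error(merge_and_split("ACGT", "III", "ACGT", "IIII", 2), "length")
  expect_error(merge_and_split("ACXT", "IIII", "ACGT", "IIII", 2), "alphabet")
  expect_error(merge_and_split("ACGT", "IIII", "ACGT", "IIII", 10), "exceeds")
  expect_error(detect_overlap("", "ACGT"), "empty")
})

test_that("FASTQ round-trips through files", {
  skip_if_not_installed("Biostrings")
  sim <- simulate_read_pairs(fragment_lengths = c(150, 300), read_length = 101,
                             seed = 5)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(tibble::tibble(id = sim$pairs$id, seq = sim$pairs$seq1,
                             qual = sim$pairs$qual1), r1)
  write_fastq(tibble::tibble(id = sim$pairs$id, seq = sim$pairs$seq2,
                             qual = sim$pairs$qual2), r2)
  pairs <- read_fastq_pairs(r1, r2)
  expect_equal(as.data.frame(pairs), as.data.frame(sim$pairs))
  out1 <- withr::local_tempfile(fileext = ".fastq")
  out2 <- withr::local_tempfile(fileext = ".fastq")
  res <- suppressMessages(merge_fastq_files(r1, r2, out1, out2))
  expect_equal(sum(res$merged), 1)
  expect_equal(nrow(read_fastq(out1)), 2)
})
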