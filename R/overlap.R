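#' Detect the R1/R2 overlap of a read pair
#'
#' Short RNA fragments sequenced in paired-end mode yield mates that overlap
#' in the middle of the fragment; counting both mates there would double-count
#' coverage. This detector finds, for each pair, the longest suffix of R1
#' matching a prefix of the reverse complement of R2 (standard FR
#' orientation) with a mismatch fraction at most `max_mismatch_rate` and
#' length at least `min_overlap`. `N` never matches anything and always
#' counts as a mismatch.
#'
#' @param seq1,seq2 Character vectors of mate sequences (alphabet `ACGTN`),
#'   recycled to a common length.
#' @param min_overlap Smallest overlap considered (default 10).
#' @param max_mismatch_rate Largest tolerated mismatch fraction inside the
#'   overlap (default 0.1; must be in `[0, 0.5)`).
#' @return Integer vector: the detected overlap length per pair, `NA` where
#'   no acceptable overlap exists.
#' @examples
#' # a 150 bp fragment read as 2 x 101 bp: geometric overlap 52
#' frag <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
#' r1 <- substr(frag, 1, 101)
#' r2 <- clonsel:::revcomp(substr(frag, 50, 150))
#' detect_overlap(r1, r2)
#' @export
detect_overlap <- function(seq1, seq2, min_overlap = 10,
                           max_mismatch_rate = 0.1) {
  if (min_overlap < 1) abort("`min_overlap` must be >= 1")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 0.5) {
    abort("`max_mismatch_rate` must be in [0, 0.5)")
  }
  n <- max(length(seq1), length(seq2))
  seq1 <- rep_len(seq1, n); seq2 <- rep_len(seq2, n)
  if (any(!nzchar(seq1)) || any(!nzchar(seq2))) abort("empty read sequence")
  vapply(seq_len(n), function(i) {
    detect_overlap_one(seq1[i], seq2[i], min_overlap, max_mismatch_rate)
  }, integer(1))
}

detect_overlap_one <- function(seq1, seq2, min_overlap, max_mismatch_rate) {
  s1 <- strsplit(seq1, "", fixed = TRUE)[[1]]
  s2 <- strsplit(revcomp(seq2), "", fixed = TRUE)[[1]]
  l1 <- length(s1); l2 <- length(s2)
  for (len in seq.int(min(l1, l2), min_overlap)) {
    a <- s1[(l1 - len + 1):l1]
    b <- s2[seq_len(len)]
    mism <- sum(a != b | a == "N" | b == "N")
    if (mism / len <= max_mismatch_rate) return(len)
  }
  NA_integer_
}

#' Merge an overlapping pair and split it into non-overlapping reads
#'
#' Reconstructs the sequenced fragment from an overlapping mate pair and
#' re-emits it as two reads that cover the fragment exactly once. Inside the
#' overlap, each base (and its quality) is taken from the mate with the
#' higher phred score, R1 winning ties. The merged fragment — of length
#' `len(R1) + len(R2) - overlap_len` — is split at `floor(len / 2)`. Pairs
#' with no detected overlap (`overlap_len` `NA` or 0) pass through
#' unchanged.
#'
#' @param seq1,qual1,seq2,qual2 One mate pair: sequences and phred+33
#'   quality strings (R2 in its stored, reverse-complemented orientation).
#' @param overlap_len Overlap from [detect_overlap()].
#' @return A one-row tibble: `merged` (logical), `seq`, `qual` (full
#'   fragment; `NA` when not merged), `overlap_len`, and the two output
#'   reads `seq_a, qual_a, seq_b, qual_b` (fragment orientation when merged,
#'   the original R1/R2 otherwise).
#' @export
merge_and_split <- function(seq1, qual1, seq2, qual2, overlap_len) {
  validate_read(seq1, qual1)
  validate_read(seq2, qual2)
  if (is.na(overlap_len) || overlap_len == 0) {
    return(tibble(merged = FALSE, seq = NA_character_, qual = NA_character_,
                  overlap_len = 0L,
                  seq_a = seq1, qual_a = qual1, seq_b = seq2, qual_b = qual2))
  }
  l1 <- nchar(seq1); l2 <- nchar(seq2)
  if (overlap_len > min(l1, l2)) {
    abort("`overlap_len` exceeds a mate length")
  }
  s1 <- strsplit(seq1, "", fixed = TRUE)[[1]]
  q1 <- utf8ToInt(qual1) - 33L
  s2 <- strsplit(revcomp(seq2), "", fixed = TRUE)[[1]]
  q2 <- rev(utf8ToInt(qual2)) - 33L

  ov <- seq_len(overlap_len)
  i1 <- l1 - overlap_len + ov           # overlap positions on R1
  from_r2 <- q2[ov] > q1[i1]            # tie -> R1
  ov_seq <- ifelse(from_r2, s2[ov], s1[i1])
  ov_qual <- ifelse(from_r2, q2[ov], q1[i1])

  seq <- c(s1[seq_len(l1 - overlap_len)], ov_seq,
           s2[seq.int(overlap_len + 1, length.out = l2 - overlap_len)])
  qual <- c(q1[seq_len(l1 - overlap_len)], ov_qual,
            q2[seq.int(overlap_len + 1, length.out = l2 - overlap_len)])
  len <- length(seq)
  cut <- floor(len / 2)
  qual_chr <- intToUtf8(qual + 33L, multiple = FALSE)
  seq_chr <- paste(seq, collapse = "")
  tibble(
    merged = TRUE, seq = seq_chr, qual = qual_chr,
    overlap_len = as.integer(overlap_len),
    seq_a = substr(seq_chr, 1, cut), qual_a = substr(qual_chr, 1, cut),
    seq_b = substr(seq_chr, cut + 1, len), qual_b = substr(qual_chr, cut + 1, len)
  )
}

validate_read <- function(seq, qual) {
  if (is.na(seq) || !nzchar(seq)) abort("empty read sequence")
  if (nchar(seq) != nchar(qual)) {
    abort("sequence and quality strings differ in length")
  }
  if (grepl("[^ACGTN]", seq)) abort("sequence outside alphabet {A,C,G,T,N}")
  invisible(TRUE)
}

#' Merge overlapping mates across a table of read pairs
#'
#' Applies [detect_overlap()] then [merge_and_split()] to every pair. Merged
#' pairs are re-emitted as two non-overlapping reads covering the fragment
#' exactly once; the second read is stored reverse-complemented so the
#' output is again a valid FR pair. Non-overlapping pairs are emitted
#' byte-identically.
#'
#' @param pairs Tibble with `id, seq1, qual1, seq2, qual2` (see
#'   [read_fastq_pairs()]).
#' @param min_overlap,max_mismatch_rate Passed to [detect_overlap()].
#' @return A tibble with one row per input pair: `id, merged, overlap_len`,
#'   output mates `out_seq1, out_qual1, out_seq2, out_qual2`, and for merged
#'   pairs the reconstructed fragment `fragment_seq, fragment_qual`.
#' @export
merge_read_pairs <- function(pairs, min_overlap = 10, max_mismatch_rate = 0.1) {
  pairs <- as_tibble(pairs)
  ov <- detect_overlap(pairs$seq1, pairs$seq2, min_overlap, max_mismatch_rate)
  res <- purrr::pmap_dfr(
    list(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2, ov),
    function(s1, q1, s2, q2, o) merge_and_split(s1, q1, s2, q2, o)
  )
  tibble(
    id = pairs$id,
    merged = res$merged,
    overlap_len = res$overlap_len,
    out_seq1 = res$seq_a,
    out_qual1 = res$qual_a,
    out_seq2 = ifelse(res$merged, revcomp(res$seq_b), res$seq_b),
    out_qual2 = ifelse(res$merged, str_rev(res$qual_b), res$qual_b),
    fragment_seq = res$seq,
    fragment_qual = res$qual
  )
}

#' Merge overlapping mates of a FASTQ pair on disk
#'
#' File-level wrapper over [merge_read_pairs()]: reads an R1/R2 FASTQ pair,
#' merges overlapping mates and writes a new, overlap-free R1/R2 pair.
#'
#' @param r1_path,r2_path Input FASTQ files.
#' @param out_r1,out_r2 Output FASTQ paths.
#' @inheritParams merge_read_pairs
#' @return Invisibly, the per-pair merge table.
#' @export
merge_fastq_files <- function(r1_path, r2_path, out_r1, out_r2,
                              min_overlap = 10, max_mismatch_rate = 0.1) {
  pairs <- read_fastq_pairs(r1_path, r2_path)
  res <- merge_read_pairs(pairs, min_overlap, max_mismatch_rate)
  write_fastq(tibble(id = res$id, seq = res$out_seq1, qual = res$out_qual1), out_r1)
  write_fastq(tibble(id = res$id, seq = res$out_seq2, qual = res$out_qual2), out_r2)
  inform(sprintf("merged %d / %d pairs", sum(res$merged), nrow(res)))
  invisible(res)
}
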