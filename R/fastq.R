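#' Read / write FASTQ as a tibble
#'
#' Thin tidy wrappers over Biostrings' FASTQ support (4-line records,
#' phred+33, gzip-transparent). Reads come back as plain character columns so
#' they compose with the rest of the pipeline.
#'
#' @param path FASTQ file path (`.gz` allowed).
#' @return `read_fastq()`: a tibble with `id, seq, qual`.
#' @export
read_fastq <- function(path) {
  require_biostrings()
  # Biostrings warns about dropping (empty) metadata columns on conversion
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  )
  tibble(
    id = names(x),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x))
  )
}

#' @rdname read_fastq
#' @param reads Tibble with `id, seq, qual`.
#' @param compress Write gzip output.
#' @export
write_fastq <- function(reads, path, compress = grepl("\\.gz$", path)) {
  require_biostrings()
  # the constructor warns about dropping (empty) metadata columns
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)
  ))
  Biostrings::writeQualityScaledXStringSet(x, path, compress = compress)
  invisible(path)
}

require_biostrings <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTQ input/output requires the Biostrings package")
  }
}

#' Read a FASTQ pair into one tibble
#'
#' @param r1_path,r2_path Mate FASTQ files, records in the same order.
#' @return Tibble with `id, seq1, qual1, seq2, qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (nrow(r1) != nrow(r2)) abort("mate files have different record counts")
  tibble(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
         seq2 = r2$seq, qual2 = r2$qual)
}

# reverse complement / reversal on plain characters
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}
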