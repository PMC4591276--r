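#' Alternative allele ratio
#'
#' The per-sample abundance measure of a variant: alternative-allele read
#' count divided by total (ref + alt) depth. Undefined (`NA`) at depth 0.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @return Numeric vector of ratios in \[0, 1\], `NA` where depth is 0 or a
#'   count is missing.
#' @examples
#' aar(65, 35)
#' @export
aar <- function(ref_count, alt_count) {
  depth <- ref_count + alt_count
  ifelse(!is.na(depth) & depth > 0, alt_count / depth, NA_real_)
}

#' Load per-sample allele counts
#'
#' Reads one sample's per-site reference/alternative allele counts, either
#' from the package's TSV dialect (header
#' `chrom pos ref alt ref_count alt_count`, tab-separated) or from a VCF with
#' a per-sample allele-depth (`AD`) FORMAT field. Multi-allelic VCF records
#' are decomposed into one row per alternative allele. Counts are assumed to
#' be restricted upstream to bases meeting the phred floor.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param sample For multi-sample VCFs, the sample column to read; defaults
#'   to the first sample.
#' @return A tibble with columns `chrom, pos, ref, alt, ref_count, alt_count,
#'   depth, aar`; `aar` is `NA` (undefined) at depth 0.
#' @export
load_sample_counts <- function(path, format = c("auto", "tsv", "vcf"),
                               sample = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  counts <- switch(format,
    tsv = load_counts_tsv(path),
    vcf = load_counts_vcf(path, sample)
  )
  counts |>
    dplyr::mutate(
      depth = .data$ref_count + .data$alt_count,
      aar = aar(.data$ref_count, .data$alt_count)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
}

load_counts_tsv <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      ref_count = readr::col_double(),
      alt_count = readr::col_double()
    ),
    progress = FALSE
  )
  required <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(is.na(x$pos) | is.na(x$ref_count) | is.na(x$alt_count) |
                 x$ref_count < 0 | x$alt_count < 0)
  if (length(bad) > 0) {
    # +1 for the header: report file line numbers, not data rows
    abort(paste0("malformed count rows in ", path, " at line(s) ",
                 paste(head(bad + 1, 5), collapse = ", ")))
  }
  as_tibble(x[required])
}

load_counts_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("AD", paste(v@gt[, "FORMAT"], collapse = ""))) {
    abort(paste0("VCF ", path, " has no per-sample AD (allele depth) field"))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  if (is.null(sample)) sample <- samples[1]
  if (!sample %in% samples) {
    abort(paste0("sample '", sample, "' not in VCF (has: ",
                 paste(samples, collapse = ", "), ")"))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad_s <- ad[, sample]
  if (anyNA(ad_s)) abort(paste0("missing AD values for sample '", sample, "'"))
  rows <- purrr::pmap(
    list(fix$CHROM, as.numeric(fix$POS), fix$REF, fix$ALT, ad_s),
    function(chrom, pos, ref, alt_field, ad_field) {
      alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
      depths <- suppressWarnings(as.numeric(strsplit(ad_field, ",", fixed = TRUE)[[1]]))
      if (length(depths) != length(alts) + 1 || anyNA(depths)) {
        abort(paste0("AD field '", ad_field, "' does not match alleles at ",
                     chrom, ":", pos))
      }
      tibble(
        chrom = chrom, pos = pos, ref = ref, alt = alts,
        ref_count = depths[1], alt_count = depths[-1]
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Build the merged variant table for a sensitive/resistant pair
#'
#' Takes per-site allele counts for the two samples (as returned by
#' [load_sample_counts()] or [simulate_pair()]) and merges them over the
#' union of variant keys `(chrom, pos, ref, alt)`, keeping every site with at
#' least one alternative-allele read in at least one sample. A site absent
#' from one sample's input is retained with that sample's counts missing
#' (`NA`) — absence of data, deliberately distinct from an observed zero.
#'
#' @param sensitive_counts,resistant_counts Tibbles with columns
#'   `chrom, pos, ref, alt, ref_count, alt_count`.
#' @return A tibble sorted by `(chrom, pos)` with per-sample columns suffixed
#'   `_s` (sensitive) and `_r` (resistant): counts, `depth_*`, `aar_*`, and
#'   presence flags `present_s`, `present_r`.
#' @examples
#' s <- tibble::tibble(chrom = "chr17", pos = 7577120, ref = "G", alt = "C",
#'                     ref_count = 100, alt_count = 0)
#' r <- dplyr::mutate(s, ref_count = 65, alt_count = 35)
#' build_merged_table(s, r)
#' @export
build_merged_table <- function(sensitive_counts, resistant_counts) {
  key <- c("chrom", "pos", "ref", "alt")
  s <- as_tibble(sensitive_counts)[c(key, "ref_count", "alt_count")]
  r <- as_tibble(resistant_counts)[c(key, "ref_count", "alt_count")]

  pos_ref <- dplyr::bind_rows(s[c("chrom", "pos", "ref")], r[c("chrom", "pos", "ref")]) |>
    dplyr::distinct() |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(pos_ref) > 0) {
    sites <- paste(pos_ref$chrom, pos_ref$pos, sep = ":")
    abort(paste0("conflicting reference allele at site(s): ",
                 paste(head(sites, 10), collapse = ", ")))
  }

  merged <- dplyr::full_join(
    dplyr::rename(s, ref_count_s = "ref_count", alt_count_s = "alt_count"),
    dplyr::rename(r, ref_count_r = "ref_count", alt_count_r = "alt_count"),
    by = key
  ) |>
    dplyr::mutate(
      present_s = !is.na(.data$ref_count_s) & !is.na(.data$alt_count_s),
      present_r = !is.na(.data$ref_count_r) & !is.na(.data$alt_count_r),
      depth_s = .data$ref_count_s + .data$alt_count_s,
      depth_r = .data$ref_count_r + .data$alt_count_r,
      aar_s = aar(.data$ref_count_s, .data$alt_count_s),
      aar_r = aar(.data$ref_count_r, .data$alt_count_r)
    ) |>
    dplyr::filter(
      (.data$present_s & .data$alt_count_s >= 1) |
        (.data$present_r & .data$alt_count_r >= 1)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)

  dupes <- merged |> dplyr::count(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dupes) > 0) {
    abort("duplicate variant keys within one sample's counts")
  }
  merged[c(key, "ref_count_s", "alt_count_s", "depth_s", "aar_s",
           "ref_count_r", "alt_count_r", "depth_r", "aar_r",
           "present_s", "present_r")]
}

#' Estimate a per-sample genotype class from allele counts
#'
#' A deliberately simple count-based estimator used only to separate
#' homozygous-reference sites from everything else, as the inclusion filter
#' requires: a site is `non_hom_ref` when it has at least 2 alternative reads
#' and an AAR of at least 0.05, `no_call` at depth 0, and `hom_ref` otherwise.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @return Character vector: `"hom_ref"`, `"non_hom_ref"` or `"no_call"`
#'   (`NA` where a count is missing).
#' @examples
#' estimate_genotype(c(50, 25, 99), c(0, 25, 1))
#' @export
estimate_genotype <- function(ref_count, alt_count) {
  depth <- ref_count + alt_count
  ratio <- aar(ref_count, alt_count)
  dplyr::case_when(
    is.na(depth) ~ NA_character_,
    depth == 0 ~ "no_call",
    alt_count >= 2 & ratio >= 0.05 ~ "non_hom_ref",
    TRUE ~ "hom_ref"
  )
}

#' Write / read a merged variant table as TSV
#'
#' @param merged A merged variant table from [build_merged_table()].
#' @param path Output file path.
#' @return `path`, invisibly (writer); the tibble (reader).
#' @export
write_merged_table <- function(merged, path) {
  readr::write_tsv(merged, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_merged_table
#' @export
read_merged_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), ref = readr::col_character(),
    alt = readr::col_character(), .default = readr::col_double(),
    present_s = readr::col_logical(), present_r = readr::col_logical()
  ), progress = FALSE)
}
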