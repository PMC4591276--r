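#' Read a variant annotation table
#'
#' Loads the Annovar-style per-variant annotation fields the inclusion filter
#' consumes, from a TSV with header `chrom pos ref alt gene location_class
#' exonic_class in_cosmic dbsnp_id ceu_af sift polyphen_hdiv in_segdup`.
#' Empty strings encode absent values (no dbSNP identifier, no population
#' frequency, no predictor call).
#'
#' @param path File path.
#' @return A tibble keyed by `(chrom, pos, ref, alt)` with logical
#'   `in_cosmic`/`in_segdup`, numeric `ceu_af` and character predictor calls.
#' @export
read_annotations <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      ref = readr::col_character(), alt = readr::col_character(),
      gene = readr::col_character(),
      location_class = readr::col_character(),
      exonic_class = readr::col_character(),
      in_cosmic = readr::col_logical(),
      dbsnp_id = readr::col_character(),
      ceu_af = readr::col_double(),
      sift = readr::col_character(),
      polyphen_hdiv = readr::col_character(),
      in_segdup = readr::col_logical()
    ),
    na = c("", "NA"), progress = FALSE
  )
  validate_annotations(x)
}

validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  required <- c("chrom", "pos", "ref", "alt", "gene", "location_class",
                "exonic_class", "in_cosmic", "dbsnp_id", "ceu_af", "sift",
                "polyphen_hdiv", "in_segdup")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_af <- !is.na(ann$ceu_af) & (ann$ceu_af < 0 | ann$ceu_af > 1)
  if (any(bad_af)) abort("ceu_af outside [0, 1]")
  if (anyNA(ann$in_cosmic) || anyNA(ann$in_segdup)) {
    abort("in_cosmic/in_segdup must be TRUE or FALSE, not missing")
  }
  n_dup <- nrow(ann) - nrow(dplyr::distinct(ann, .data$chrom, .data$pos,
                                            .data$ref, .data$alt))
  if (n_dup > 0) abort("duplicate annotation keys")
  ann[required]
}

#' Apply the annotation-driven inclusion decision tree
#'
#' Evaluates, for every merged-table record, the ordered inclusion rules of
#' the analysis and returns a full audit trail. A variant is included iff all
#' of the following hold:
#'
#' 1. its genotype is non-homozygous-reference in at least one sample;
#' 2. both samples have strictly more than `depth_min_strict` reads;
#' 3. it is exonic and not synonymous;
#' 4. it is not in a segmental-duplication region;
#' 5. one evidence branch passes:
#'    (a) in COSMIC, with 1000g CEU allele frequency absent or below
#'        `ceu_af_max`;
#'    (b) novel (no CEU frequency, no dbSNP id) and SIFT *or* PolyPhen-2 HDIV
#'        calls it deleterious;
#'    (c) dbSNP-known but CEU-absent and *both* predictors call it
#'        deleterious.
#'
#' Records with no annotation are excluded and flagged `annotated = FALSE`.
#'
#' @param merged Merged variant table from [build_merged_table()].
#' @param annotations Annotation tibble from [read_annotations()] (or
#'   [simulate_pair()]).
#' @param thresholds A [clonsel_thresholds()] object (or `NULL` for defaults).
#' @param cosmic_match `"allele"` (default): COSMIC membership is taken from
#'   the record's own annotation; `"position"`: a variant counts as in COSMIC
#'   when any allele at its position is.
#' @return The merged table joined to its annotations, with one logical audit
#'   column per rule (`rule_genotype`, `rule_depth`, `rule_coding`,
#'   `rule_segdup`, `rule_evidence`), the passing `evidence_branch`
#'   (`"cosmic"`, `"novel_predicted"`, `"dbsnp_predicted"` or `NA`),
#'   `annotated`, and the final `include` flag.
#' @seealso [filter_variants()] for the included subset only.
#' @export
variant_inclusion <- function(merged, annotations, thresholds = NULL,
                              cosmic_match = c("allele", "position")) {
  th <- as_thresholds(thresholds)
  cosmic_match <- match.arg(cosmic_match)
  ann <- validate_annotations(annotations)
  if (cosmic_match == "position") {
    ann <- ann |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::mutate(in_cosmic = any(.data$in_cosmic)) |>
      dplyr::ungroup()
  }
  x <- dplyr::left_join(as_tibble(merged), dplyr::mutate(ann, annotated = TRUE),
                        by = c("chrom", "pos", "ref", "alt"))
  x |>
    dplyr::mutate(
      annotated = !is.na(.data$annotated),
      genotype_s = estimate_genotype(.data$ref_count_s, .data$alt_count_s),
      genotype_r = estimate_genotype(.data$ref_count_r, .data$alt_count_r),
      rule_genotype =
        (!is.na(.data$genotype_s) & .data$genotype_s == "non_hom_ref") |
        (!is.na(.data$genotype_r) & .data$genotype_r == "non_hom_ref"),
      rule_depth =
        !is.na(.data$depth_s) & !is.na(.data$depth_r) &
        .data$depth_s > th$depth_min_strict & .data$depth_r > th$depth_min_strict,
      rule_coding = .data$annotated &
        !is.na(.data$location_class) & .data$location_class == "exonic" &
        !is.na(.data$exonic_class) & .data$exonic_class != "synonymous",
      rule_segdup = .data$annotated & !.data$in_segdup,
      branch_cosmic = .data$annotated & .data$in_cosmic &
        (is.na(.data$ceu_af) | .data$ceu_af < th$ceu_af_max),
      branch_novel = .data$annotated &
        is.na(.data$ceu_af) & is.na(.data$dbsnp_id) &
        ((!is.na(.data$sift) & .data$sift == "deleterious") |
           (!is.na(.data$polyphen_hdiv) & .data$polyphen_hdiv == "deleterious")),
      branch_dbsnp = .data$annotated &
        is.na(.data$ceu_af) & !is.na(.data$dbsnp_id) &
        (!is.na(.data$sift) & .data$sift == "deleterious") &
        (!is.na(.data$polyphen_hdiv) & .data$polyphen_hdiv == "deleterious"),
      rule_evidence = .data$branch_cosmic | .data$branch_novel | .data$branch_dbsnp,
      evidence_branch = dplyr::case_when(
        branch_cosmic ~ "cosmic",
        branch_novel ~ "novel_predicted",
        branch_dbsnp ~ "dbsnp_predicted",
        TRUE ~ NA_character_
      ),
      include = .data$annotated & .data$rule_genotype & .data$rule_depth &
        .data$rule_coding & .data$rule_segdup & .data$rule_evidence
    ) |>
    dplyr::select(-"branch_cosmic", -"branch_novel", -"branch_dbsnp")
}

#' Filter a merged variant table to the included variants
#'
#' Convenience wrapper around [variant_inclusion()] that keeps only the
#' records passing every rule, and reports stage counts as attributes.
#'
#' @inheritParams variant_inclusion
#' @return The included records (with annotation columns), with an attribute
#'   `filter_counts`: a named vector of record counts entering, unannotated,
#'   failing, and passing.
#' @export
filter_variants <- function(merged, annotations, thresholds = NULL,
                            cosmic_match = c("allele", "position")) {
  audit <- variant_inclusion(merged, annotations, thresholds, cosmic_match)
  out <- dplyr::filter(audit, .data$include)
  attr(out, "filter_counts") <- c(
    total = nrow(audit),
    unannotated = sum(!audit$annotated),
    excluded = sum(audit$annotated & !audit$include),
    included = nrow(out)
  )
  out
}

#' Write the inclusion audit trail
#'
#' @param audit Result of [variant_inclusion()].
#' @param path Output TSV path.
#' @export
write_inclusion_audit <- function(audit, path) {
  readr::write_tsv(audit, path, progress = FALSE)
  invisible(path)
}
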