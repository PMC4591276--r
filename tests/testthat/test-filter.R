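# one merged-table record + one annotation record, with overridable fields
mk_record <- function(ref_s = 100, alt_s = 50, ref_r = 100, alt_r = 50) {
  tibble::tibble(
    chrom = "chr1", pos = 1000, ref = "A", alt = "T",
    ref_count_s = ref_s, alt_count_s = alt_s,
    ref_count_r = ref_r, alt_count_r = alt_r,
    depth_s = ref_s + alt_s, depth_r = ref_r + alt_r,
    aar_s = aar(ref_s, alt_s), aar_r = aar(ref_r, alt_r),
    present_s = TRUE, present_r = TRUE
  )
}

mk_ann <- function(gene = "G1", location_class = "exonic",
                   exonic_class = "nonsynonymous", in_cosmic = FALSE,
                   dbsnp_id = NA_character_, ceu_af = NA_real_,
                   sift = NA_character_, polyphen_hdiv = NA_character_,
                   in_segdup = FALSE) {
  tibble::tibble(
    chrom = "chr1", pos = 1000, ref = "A", alt = "T", gene = gene,
    location_class = location_class, exonic_class = exonic_class,
    in_cosmic = in_cosmic, dbsnp_id = dbsnp_id, ceu_af = ceu_af,
    sift = sift, polyphen_hdiv = polyphen_hdiv, in_segdup = in_segdup
  )
}

include_of <- function(record, ann, ...) {
  variant_inclusion(record, ann, ...)$include
}

test_that("the published decision-tree examples are reproduced", {
  # recurrent-oncogene pattern: COSMIC, no population frequency, deep coverage
  expect_true(include_of(mk_record(150, 0, 119, 21), mk_ann(in_cosmic = TRUE)))
  # synonymous exonic change fails the coding rule
  expect_false(include_of(mk_record(), mk_ann(in_cosmic = TRUE,
                                              exonic_class = "synonymous")))
  # segmental duplication excludes regardless of all other evidence
  expect_false(include_of(mk_record(), mk_ann(in_cosmic = TRUE, in_segdup = TRUE)))
  # novel variant with neither predictor deleterious
  expect_false(include_of(mk_record(), mk_ann(sift = "tolerated",
                                              polyphen_hdiv = "benign")))
  # novel with one deleterious call suffices
  expect_true(include_of(mk_record(), mk_ann(sift = "deleterious",
                                             polyphen_hdiv = "benign")))
  # dbSNP-known needs both predictors deleterious
  expect_false(include_of(mk_record(), mk_ann(dbsnp_id = "rs1", sift = "deleterious",
                                              polyphen_hdiv = "benign")))
  expect_true(include_of(mk_record(), mk_ann(dbsnp_id = "rs1", sift = "deleterious",
                                             polyphen_hdiv = "deleterious")))
  # possibly_damaging is not deleterious
  expect_false(include_of(mk_record(), mk_ann(dbsnp_id = "rs1", sift = "deleterious",
                                              polyphen_hdiv = "possibly_damaging")))
  # common CEU polymorphism blocks the COSMIC branch
  expect_false(include_of(mk_record(), mk_ann(in_cosmic = TRUE, ceu_af = 0.3)))
  expect_true(include_of(mk_record(), mk_ann(in_cosmic = TRUE, ceu_af = 0.01)))
  # CEU-present but non-COSMIC variants have no inclusion path
  expect_false(include_of(mk_record(), mk_ann(ceu_af = 0.01, sift = "deleterious",
                                              polyphen_hdiv = "deleterious")))
})

test_that("depth and genotype gates apply to the counts", {
  # exactly 10 reads in one sample: excluded (strictly more than 10 required)
  expect_false(include_of(mk_record(5, 5, 100, 50), mk_ann(in_cosmic = TRUE)))
  expect_true(include_of(mk_record(6, 5, 100, 50), mk_ann(in_cosmic = TRUE)))
  # hom-ref in both samples: excluded even with strong annotation
  expect_false(include_of(mk_record(100, 1, 100, 1), mk_ann(in_cosmic = TRUE)))
  # non-hom-ref in only one sample is enough (de-novo appearing variant)
  expect_true(include_of(mk_record(100, 0, 65, 35), mk_ann(in_cosmic = TRUE)))
  # missing counts in one sample fail the depth rule
  rec <- mk_record(100, 0, 65, 35)
  rec$ref_count_s <- NA; rec$alt_count_s <- NA
  rec$depth_s <- NA; rec$aar_s <- NA; rec$present_s <- FALSE
  expect_false(include_of(rec, mk_ann(in_cosmic = TRUE)))
})

test_that("decision equals a brute-force truth-table over rule inputs", {
  # independent re-statement of the tree as one boolean expression
  oracle_include <- function(non_hom_ref_any, deep_both, exonic, nonsyn,
                             segdup, cosmic, has_ceu, low_ceu, has_dbsnp,
                             sift_del, poly_del) {
    evidence <- (cosmic && (!has_ceu || low_ceu)) ||
      (!has_ceu && !has_dbsnp && (sift_del || poly_del)) ||
      (!has_ceu && has_dbsnp && sift_del && poly_del)
    non_hom_ref_any && deep_both && exonic && nonsyn && !segdup && evidence
  }
  grid <- expand.grid(genotype_ok = c(TRUE, FALSE), deep = c(TRUE, FALSE),
                      exonic = c(TRUE, FALSE), nonsyn = c(TRUE, FALSE),
                      segdup = c(TRUE, FALSE), cosmic = c(TRUE, FALSE),
                      has_ceu = c(TRUE, FALSE), low_ceu = c(TRUE, FALSE),
                      has_dbsnp = c(TRUE, FALSE), sift_del = c(TRUE, FALSE),
                      poly_del = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- if (g$genotype_ok) mk_record(100, 50, 100, 50) else mk_record(100, 1, 100, 1)
    if (!g$deep) { rec$ref_count_s <- 5; rec$alt_count_s <- if (g$genotype_ok) 5 else 0
                   rec$depth_s <- rec$ref_count_s + rec$alt_count_s
                   rec$aar_s <- aar(rec$ref_count_s, rec$alt_count_s) }
    ann <- mk_ann(
      location_class = if (g$exonic) "exonic" else "intronic",
      exonic_class = if (g$nonsyn) "nonsynonymous" else "synonymous",
      in_cosmic = g$cosmic, in_segdup = g$segdup,
      ceu_af = if (g$has_ceu) { if (g$low_ceu) 0.01 else 0.3 } else NA_real_,
      dbsnp_id = if (g$has_dbsnp) "rs1" else NA_character_,
      sift = if (g$sift_del) "deleterious" else "tolerated",
      polyphen_hdiv = if (g$poly_del) "deleterious" else "benign"
    )
    # deep genotype-failing record: keep depth adequate so rules separate
    genotype_any <- g$genotype_ok
    deep_both <- g$deep
    expected <- oracle_include(genotype_any, deep_both, g$exonic, g$nonsyn,
                               g$segdup, g$cosmic, g$has_ceu, g$low_ceu,
                               g$has_dbsnp, g$sift_del, g$poly_del)
    expect_identical(include_of(rec, ann), expected)
  }
})

test_that("adding COSMIC evidence is monotone", {
  set.seed(11)
  for (i in 1:50) {
    ann <- mk_ann(
      in_cosmic = FALSE,
      dbsnp_id = sample(c("rs1", NA_character_), 1),
      ceu_af = sample(c(NA_real_, 0.01), 1),
      sift = sample(c("deleterious", "tolerated", NA_character_), 1),
      polyphen_hdiv = sample(c("deleterious", "benign", NA_character_), 1),
      in_segdup = sample(c(TRUE, FALSE), 1),
      exonic_class = sample(c("nonsynonymous", "synonymous"), 1)
    )
    rec <- mk_record()
    before <- include_of(rec, ann)
    ann$in_cosmic <- TRUE
    after <- include_of(rec, ann)
    if (before) expect_true(after)
  }
})

test_that("the audit trace has a verdict for every rule, in fixed order", {
  audit <- variant_inclusion(mk_record(), mk_ann(in_cosmic = TRUE))
  rule_cols <- c("rule_genotype", "rule_depth", "rule_coding", "rule_segdup",
                 "rule_evidence")
  expect_true(all(rule_cols %in% names(audit)))
  expect_equal(rule_cols, names(audit)[names(audit) %in% rule_cols])
  expect_false(anyNA(audit[rule_cols]))
  expect_equal(audit$evidence_branch, "cosmic")
})

test_that("unannotated records are excluded and counted separately", {
  rec <- dplyr::bind_rows(mk_record(), dplyr::mutate(mk_record(), pos = 2000))
  ann <- mk_ann(in_cosmic = TRUE)  # only pos 1000
  out <- filter_variants(rec, ann)
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["unannotated"]), 1)
  expect_equal(unname(counts["included"]), 1)
  expect_equal(unname(counts[["total"]]),
               unname(counts[["unannotated"]] + counts[["excluded"]] +
                        counts[["included"]]))
})

test_that("position-mode COSMIC matching borrows membership across alleles", {
  rec <- mk_record()
  ann <- dplyr::bind_rows(
    mk_ann(in_cosmic = FALSE),
    dplyr::mutate(mk_ann(in_cosmic = TRUE), alt = "G")
  )
  expect_false(include_of(rec, ann, cosmic_match = "allele")[1])
  expect_true(include_of(rec, ann, cosmic_match = "position")[1])
})
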