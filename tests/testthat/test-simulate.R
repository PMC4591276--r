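small_model <- function(...) {
  defaults <- list(n_ancestral_variants = 60, n_selected_variants = 15,
                   n_depleted_variants = 8, n_hom_ref_sites = 40)
  do.call(clone_model, utils::modifyList(defaults, list(...)))
}

test_that("clone model validation rejects impossible parameters", {
  expect_error(clone_model(ancestral_fraction = 1.2), "\\[0, 1\\]")
  expect_error(clone_model(n_selected_variants = -1), "non-negative")
  expect_error(clone_model(mean_depth = 0), "positive")
  expect_error(simulate_pair(small_model(),
                             ploidy_plan = dplyr::mutate(default_ploidy_plan(),
                                                         m_s = k_s)),
               "m <= k - 1")
})

test_that("identical seeds give identical simulations", {
  a <- simulate_pair(small_model(), seed = 99)
  b <- simulate_pair(small_model(), seed = 99)
  expect_identical(a$sensitive, b$sensitive)
  expect_identical(a$resistant, b$resistant)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  c <- simulate_pair(small_model(), seed = 100)
  expect_false(identical(a$sensitive, c$sensitive))
  # the global RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); simulate_pair(small_model(), seed = 5); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("truth category counts equal the requested counts exactly", {
  sim <- simulate_pair(small_model(), seed = 12)
  counts <- dplyr::count(sim$truth, category)
  expect_equal(counts$n[counts$category == "ancestral"], 60)
  expect_equal(counts$n[counts$category == "selected_up"], 15)
  expect_equal(counts$n[counts$category == "selected_down"], 8)
  # every simulated variant appears exactly once
  expect_equal(nrow(sim$truth),
               nrow(dplyr::distinct(sim$truth, chrom, pos, ref, alt)))
  expect_equal(nrow(sim$truth), nrow(sim$sensitive))
  expect_equal(nrow(sim$truth), nrow(sim$annotations))
})

test_that("planted AARs follow the clone-fraction formula", {
  sim <- simulate_pair(small_model(ancestral_fraction = 0.8), seed = 21)
  tr <- sim$truth
  anc <- dplyr::filter(tr, category == "ancestral")
  # ancestral variants live on configuration-shared segments
  expect_equal(anc$true_aar_s, anc$true_aar_r)
  expect_equal(anc$true_aar_s, 0.8 * anc$m_alt_s / anc$k_s)
  sel <- dplyr::filter(tr, category == "selected_up")
  expect_true(all(sel$true_aar_s == 0))
  expect_equal(sel$true_aar_r, 0.7 * sel$m_alt_r / sel$k_r)
  # the de-novo pattern: a diploid-region subclone variant at fraction 0.7
  # has true AARs 0 and 0.35
  dip <- dplyr::filter(sel, k_r == 2, m_alt_r == 1)
  expect_true(nrow(dip) > 0)
  expect_equal(unique(dip$true_aar_r), 0.35)
  # category consistency: planted selection implies the planted shift
  expect_true(all(sel$true_aar_r - sel$true_aar_s > 0))
})

test_that("empirical mean AAR converges to the planted value", {
  sim <- simulate_pair(clone_model(n_ancestral_variants = 2000,
                                   n_selected_variants = 0,
                                   n_depleted_variants = 0,
                                   n_hom_ref_sites = 0,
                                   ancestral_fraction = 1),
                       seed = 31)
  merged <- build_merged_table(sim$sensitive, sim$resistant)
  tr <- dplyr::inner_join(merged, sim$truth, by = c("chrom", "pos", "ref", "alt"))
  # diploid ancestral het variants: planted AAR 1/2
  dip <- dplyr::filter(tr, k_s == 2, !is.na(aar_s))
  se <- stats::sd(dip$aar_s) / sqrt(nrow(dip))
  expect_lt(abs(mean(dip$aar_s) - 0.5), 3 * se)
})

test_that("with no subclone anywhere all somatic AARs are the ancestral level", {
  sim <- simulate_pair(small_model(resistant_subclone_fraction_resistant = 0,
                                   n_selected_variants = 5,
                                   n_depleted_variants = 0),
                       seed = 41)
  sel <- dplyr::filter(sim$truth, category == "selected_up")
  expect_true(all(sel$true_aar_s == 0 & sel$true_aar_r == 0))
  anc <- dplyr::filter(sim$truth, category == "ancestral", k_s == 2)
  expect_true(all(anc$true_aar_s == 0.5))
})

test_that("annotations exercise every branch of the decision tree", {
  sim <- simulate_pair(small_model(), seed = 51)
  ann <- dplyr::inner_join(sim$annotations,
                           sim$truth[c("chrom", "pos", "ref", "alt", "category")],
                           by = c("chrom", "pos", "ref", "alt"))
  sel <- dplyr::filter(ann, category %in% c("selected_up", "selected_down"))
  expect_true(all(sel$in_cosmic))
  expect_true(all(sel$location_class == "exonic" &
                    sel$exonic_class == "nonsynonymous"))
  neu <- dplyr::filter(ann, category == "neutral")
  expect_true(any(neu$in_segdup))
  expect_lt(mean(neu$in_segdup), 0.25)
  expect_true(all(neu$ceu_af >= 0.05, na.rm = TRUE))
})

test_that("simulated expression respects the planted plan", {
  plan <- default_de_plan(500)
  expect_error(simulate_expression(100, tibble::tibble(gene_idx = 1,
                                                       fold_change = -2)),
               "positive")
  a <- simulate_expression(500, plan, seed = 8)
  b <- simulate_expression(500, plan, seed = 8)
  expect_identical(a$counts, b$counts)
  # one gene is planted at 17-fold repression
  expect_true(any(abs(a$truth$fold_change - 1 / 17) < 1e-12))
  expect_equal(sum(a$truth$planted_de), nrow(plan))
  # null genes share means: global normalized ratio near 1
  null_genes <- dplyr::filter(dplyr::inner_join(a$counts, a$truth, by = "gene"),
                              !planted_de)
  expect_equal(sum(null_genes$count_r) / sum(null_genes$count_s), 1,
               tolerance = 0.05)
})

test_that("simulated read pairs follow the overlap geometry", {
  expect_message(
    sim <- simulate_read_pairs(fragment_lengths = c(300, 150, 101, 90),
                               read_length = 101, seed = 2),
    "skipped 1 fragment"
  )
  expect_equal(nrow(sim$pairs), 3)
  expect_equal(sim$skipped, 90)
  expect_equal(sim$truth$overlap_len, c(0L, 52L, 101L))
  expect_equal(nchar(sim$pairs$seq1), rep(101, 3))
  a <- simulate_read_pairs(fragment_lengths = c(150), seed = 9)
  b <- simulate_read_pairs(fragment_lengths = c(150), seed = 9)
  expect_identical(a$pairs, b$pairs)
})

test_that("a simulated pair writes to plain-text files", {
  sim <- simulate_pair(small_model(), seed = 61)
  dir <- withr::local_tempdir()
  paths <- write_simulated_pair(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- load_sample_counts(paths[["sensitive"]])
  expect_equal(nrow(back), nrow(sim$sensitive))
  segs <- read_segment_bed(paths[["segments"]])
  expect_equal(nrow(segs), nrow(sim$segments))
  expect_equal(segs$start, sim$segments$start)
})
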