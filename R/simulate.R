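#' Specify the clonal structure of a simulated sensitive/resistant pair
#'
#' The generator models an ancestral tumor clone present in both samples and
#' a resistant subclone that is (essentially) absent before treatment and
#' expands under drug pressure, plus a depleted clone that shrinks — the
#' structure inferred from paired sensitive/resistant sequencing. The true
#' alternative allele ratio (AAR) of a variant carried on `m_alt` of a
#' region's `k` parental alleles by a clone at cell fraction `f` is
#' `f * m_alt / k`.
#'
#' @param ancestral_fraction Cell fraction of the ancestral clone in both
#'   samples (tumor purity), in `[0, 1]`.
#' @param resistant_subclone_fraction_sensitive Cell fraction of the
#'   resistant subclone before treatment (expected close to 0).
#' @param resistant_subclone_fraction_resistant Its fraction after treatment,
#'   in `(0, 1]`.
#' @param n_ancestral_variants,n_selected_variants,n_depleted_variants
#'   Numbers of planted ancestral, positively selected (subclone-private) and
#'   negatively selected (depleted-clone) variants.
#' @param n_hom_ref_sites Truly homozygous-reference sites carried along to
#'   exercise the sequencing-error path and the at-least-one-alt-read
#'   table-inclusion rule.
#' @param mean_depth Mean per-site read depth.
#' @param depth_dispersion Negative-binomial size parameter of the per-site
#'   depth (variance `mu + mu^2 / size`); smaller is more overdispersed.
#' @param error_rate Per-base sequencing error rate applied at
#'   homozygous-reference sites (default 0.1%).
#' @return A validated `clone_model` list.
#' @export
clone_model <- function(ancestral_fraction = 1,
                        resistant_subclone_fraction_sensitive = 0,
                        resistant_subclone_fraction_resistant = 0.7,
                        n_ancestral_variants = 200,
                        n_selected_variants = 20,
                        n_depleted_variants = 10,
                        n_hom_ref_sites = 300,
                        mean_depth = 100,
                        depth_dispersion = 10,
                        error_rate = 0.001) {
  model <- list(
    ancestral_fraction = ancestral_fraction,
    resistant_subclone_fraction_sensitive = resistant_subclone_fraction_sensitive,
    resistant_subclone_fraction_resistant = resistant_subclone_fraction_resistant,
    n_ancestral_variants = n_ancestral_variants,
    n_selected_variants = n_selected_variants,
    n_depleted_variants = n_depleted_variants,
    n_hom_ref_sites = n_hom_ref_sites,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate
  )
  fracs <- model[c("ancestral_fraction", "resistant_subclone_fraction_sensitive",
                   "resistant_subclone_fraction_resistant")]
  if (!all(vapply(fracs, function(x) is.numeric(x) && x >= 0 && x <= 1, logical(1)))) {
    abort("clone fractions must lie in [0, 1]")
  }
  counts <- model[c("n_ancestral_variants", "n_selected_variants",
                    "n_depleted_variants", "n_hom_ref_sites")]
  if (!all(vapply(counts, function(x) x >= 0 && x == floor(x), logical(1)))) {
    abort("variant counts must be non-negative integers")
  }
  if (model$mean_depth <= 0 || model$depth_dispersion <= 0) {
    abort("mean_depth and depth_dispersion must be positive")
  }
  if (model$error_rate < 0 || model$error_rate > 0.5) {
    abort("error_rate must lie in [0, 0.5]")
  }
  structure(model, class = "clone_model")
}

#' Default ploidy plan for the simulated genome
#'
#' A small synthetic genome of cytoband-scale segments with the qualitative
#' patterns seen in paired tumor samples: a resistant-only unbalanced
#' tetraploid segment, a resistant-only unbalanced pentaploid segment, a
#' sensitive-only triploid segment, and balanced (1:1) background. Columns
#' `k_s, m_s` / `k_r, m_r` give each sample's total parental alleles and
#' major-haplotype copies; `n_het_sites` the number of germline heterozygous
#' sites simulated per segment.
#'
#' @param n_het_sites Het sites per segment (default 80).
#' @return A tibble usable as `ploidy_plan` in [simulate_pair()].
#' @export
default_ploidy_plan <- function(n_het_sites = 80) {
  tibble(
    chrom = paste0("chr", 1:5),
    start = 1,
    end = 2e6,
    k_s = c(2, 2, 2, 3, 2),
    m_s = c(1, 1, 1, 2, 1),
    k_r = c(2, 4, 5, 2, 2),
    m_r = c(1, 3, 4, 1, 1),
    n_het_sites = n_het_sites
  )
}

#' Default annotation plan
#'
#' Mixture weights controlling how simulated variants are annotated, chosen
#' to exercise every branch of the inclusion decision tree: planted selected
#' and depleted variants are COSMIC-listed exonic nonsynonymous changes;
#' ancestral variants are a COSMIC / novel-deleterious mixture; germline and
#' noise sites draw dbSNP identifiers, common CEU frequencies, tolerated
#' predictor calls, synonymous or non-exonic classes, and a configurable
#' fraction of segmental-duplication flags.
#'
#' @param p_segdup_neutral Fraction of neutral variants flagged as segmental
#'   duplication (default 0.1).
#' @param p_cosmic_ancestral Fraction of ancestral variants annotated as
#'   COSMIC (the rest are novel with a deleterious predictor call).
#' @return A named list.
#' @export
default_annotation_plan <- function(p_segdup_neutral = 0.1,
                                    p_cosmic_ancestral = 0.6) {
  list(p_segdup_neutral = p_segdup_neutral,
       p_cosmic_ancestral = p_cosmic_ancestral)
}

#' Simulate a sensitive/resistant sample pair with known truth
#'
#' Generates per-sample allele counts at simulated transcriptome positions,
#' an annotation table, and a per-variant truth table, for a tumor with the
#' clonal structure of `model` over the regional ploidy states of
#' `ploidy_plan`. Per-site depths are negative-binomial
#' (`mean_depth`, `depth_dispersion`); alternative-allele counts are
#' binomial with success probability equal to the variant's true AAR in that
#' sample; homozygous-reference sites draw alt reads at `error_rate`.
#' Identical seeds give identical output.
#'
#' @param model A [clone_model()].
#' @param ploidy_plan Segment tibble (see [default_ploidy_plan()]).
#' @param annotation_plan Named list (see [default_annotation_plan()]).
#' @param seed Integer seed; all randomness derives from it and the global
#'   RNG state is left untouched.
#' @return A list of class `clonsel_sim`: `sensitive` and `resistant` count
#'   tibbles (`chrom, pos, ref, alt, ref_count, alt_count`), `annotations`,
#'   `truth` (per-variant `category`, true AARs, segment, allele
#'   configuration), and `segments` (the plan, with per-sample truth
#'   labels).
#' @examples
#' sim <- simulate_pair(clone_model(n_ancestral_variants = 20,
#'                                  n_selected_variants = 5,
#'                                  n_depleted_variants = 2,
#'                                  n_hom_ref_sites = 10), seed = 1)
#' dplyr::count(sim$truth, category)
#' @export
simulate_pair <- function(model = clone_model(),
                          ploidy_plan = default_ploidy_plan(),
                          annotation_plan = default_annotation_plan(),
                          seed = 1) {
  if (!inherits(model, "clone_model")) model <- do.call(clone_model, as.list(model))
  plan <- as_tibble(ploidy_plan)
  need <- c("chrom", "start", "end", "k_s", "m_s", "k_r", "m_r", "n_het_sites")
  if (!all(need %in% names(plan))) {
    abort(paste0("ploidy_plan needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(plan$k_s < 2) || any(plan$k_r < 2) ||
      any(plan$m_s < 1 | plan$m_s > plan$k_s - 1) ||
      any(plan$m_r < 1 | plan$m_r > plan$k_r - 1)) {
    abort("allelic configurations must satisfy k >= 2 and 1 <= m <= k - 1")
  }
  withr::with_seed(seed, simulate_pair_impl(model, plan, annotation_plan))
}

simulate_pair_impl <- function(model, plan, ann_plan) {
  n_seg <- nrow(plan)
  counts <- c(
    ancestral = model$n_ancestral_variants,
    selected_up = model$n_selected_variants,
    selected_down = model$n_depleted_variants,
    neutral_noise = model$n_hom_ref_sites
  )
  n_het <- sum(plan$n_het_sites)

  variants <- tibble(
    category = c(
      rep("ancestral", counts["ancestral"]),
      rep("selected_up", counts["selected_up"]),
      rep("selected_down", counts["selected_down"]),
      rep("neutral", n_het + counts["neutral_noise"]),
      NULL
    ),
    kind = c(
      rep("somatic", sum(counts[1:3])),
      rep("germline_het", n_het),
      rep("hom_ref", counts["neutral_noise"])
    )
  )
  n <- nrow(variants)

  # segment assignment: germline het sites follow the plan exactly; noise
  # sites are spread uniformly; somatic variants go only to segments whose
  # allelic configuration is shared by both samples, so that a planted
  # category is consistent with its planted AARs (a ploidy change would
  # shift an ancestral variant's AAR without any clonal selection)
  seg_idx <- integer(n)
  seg_idx[variants$kind == "germline_het"] <- rep(seq_len(n_seg), plan$n_het_sites)
  hom0 <- variants$kind == "hom_ref"
  seg_idx[hom0] <- sample.int(n_seg, sum(hom0), replace = TRUE)
  shared <- which(plan$k_s == plan$k_r & plan$m_s == plan$m_r)
  if (length(shared) == 0) {
    abort("ploidy_plan needs at least one segment with the same configuration in both samples to host somatic variants")
  }
  som <- variants$kind == "somatic"
  seg_idx[som] <- shared[sample.int(length(shared), sum(som), replace = TRUE)]
  variants$segment <- seg_idx

  # unique positions within each segment
  variants$pos <- NA_real_
  for (g in seq_len(n_seg)) {
    in_g <- which(seg_idx == g)
    variants$pos[in_g] <- sample(seq.int(plan$start[g], plan$end[g]),
                                 length(in_g), replace = FALSE)
  }
  variants$chrom <- plan$chrom[seg_idx]
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, n, replace = TRUE)
  variants$alt <- vapply(variants$ref,
                         function(b) sample(setdiff(bases, b), 1), character(1))

  # each variant-bearing haplotype is drawn once and kept across samples;
  # haplotype 1 has m copies, haplotype 2 has k - m
  hap <- sample(1:2, n, replace = TRUE)
  m_alt_s <- ifelse(hap == 1, plan$m_s[seg_idx], plan$k_s[seg_idx] - plan$m_s[seg_idx])
  m_alt_r <- ifelse(hap == 1, plan$m_r[seg_idx], plan$k_r[seg_idx] - plan$m_r[seg_idx])
  frac_s <- dplyr::case_when(
    variants$category == "ancestral" ~ model$ancestral_fraction,
    variants$category == "selected_up" ~ model$resistant_subclone_fraction_sensitive,
    variants$category == "selected_down" ~ model$resistant_subclone_fraction_resistant,
    variants$kind == "germline_het" ~ 1,
    TRUE ~ 0
  )
  frac_r <- dplyr::case_when(
    variants$category == "ancestral" ~ model$ancestral_fraction,
    variants$category == "selected_up" ~ model$resistant_subclone_fraction_resistant,
    variants$category == "selected_down" ~ model$resistant_subclone_fraction_sensitive,
    variants$kind == "germline_het" ~ 1,
    TRUE ~ 0
  )
  variants$true_aar_s <- frac_s * m_alt_s / plan$k_s[seg_idx]
  variants$true_aar_r <- frac_r * m_alt_r / plan$k_r[seg_idx]
  hom <- variants$kind == "hom_ref"
  variants$true_aar_s[hom] <- 0
  variants$true_aar_r[hom] <- 0

  draw_counts <- function(true_aar) {
    depth <- rnbinom(n, size = model$depth_dispersion, mu = model$mean_depth)
    p <- ifelse(hom, model$error_rate, true_aar)
    alt <- rbinom(n, depth, p)
    tibble(ref_count = depth - alt, alt_count = alt)
  }
  cs <- draw_counts(variants$true_aar_s)
  cr <- draw_counts(variants$true_aar_r)

  key <- variants[c("chrom", "pos", "ref", "alt")]
  sensitive <- dplyr::bind_cols(key, cs) |> dplyr::arrange(.data$chrom, .data$pos)
  resistant <- dplyr::bind_cols(key, cr) |> dplyr::arrange(.data$chrom, .data$pos)

  annotations <- simulate_annotations(variants, ann_plan)

  truth <- dplyr::bind_cols(
    key,
    variants[c("category", "kind", "segment", "true_aar_s", "true_aar_r")],
    tibble(haplotype = hap, m_alt_s = m_alt_s, m_alt_r = m_alt_r,
           k_s = plan$k_s[seg_idx], k_r = plan$k_r[seg_idx])
  ) |> dplyr::arrange(.data$chrom, .data$pos)

  segments <- plan |>
    dplyr::mutate(
      label_s = ploidy_label(.data$k_s, .data$m_s / .data$k_s == 0.5),
      label_r = ploidy_label(.data$k_r, .data$m_r / .data$k_r == 0.5)
    )

  structure(
    list(sensitive = sensitive, resistant = resistant,
         annotations = annotations, truth = truth, segments = segments,
         model = model),
    class = "clonsel_sim"
  )
}

simulate_annotations <- function(variants, ann_plan) {
  n <- nrow(variants)
  gene <- sprintf("G%05d", seq_len(n))
  somatic <- variants$kind == "somatic"
  neutral <- !somatic

  in_cosmic <- logical(n)
  dbsnp_id <- rep(NA_character_, n)
  ceu_af <- rep(NA_real_, n)
  sift <- rep(NA_character_, n)
  polyphen <- rep(NA_character_, n)
  location <- rep("exonic", n)
  exonic_class <- rep("nonsynonymous", n)
  in_segdup <- logical(n)

  # selected / depleted: recurrent somatic events -> COSMIC branch
  sel <- variants$category %in% c("selected_up", "selected_down")
  in_cosmic[sel] <- TRUE
  # ancestral: COSMIC mixture, remainder novel with a deleterious call
  anc <- which(variants$category == "ancestral")
  is_cos <- runif(length(anc)) < ann_plan$p_cosmic_ancestral
  in_cosmic[anc[is_cos]] <- TRUE
  novel <- anc[!is_cos]
  use_sift <- runif(length(novel)) < 0.5
  sift[novel[use_sift]] <- "deleterious"
  polyphen[novel[use_sift]] <- sample(c("benign", "possibly_damaging"),
                                      sum(use_sift), replace = TRUE)
  sift[novel[!use_sift]] <- "tolerated"
  polyphen[novel[!use_sift]] <- "deleterious"

  # neutral sites: common germline polymorphisms and artifacts the decision
  # tree must reject
  neu <- which(neutral)
  if (length(neu) > 0) {
    dbsnp_id[neu] <- sprintf("rs%07d", sample.int(9999999, length(neu)))
    ceu_af[neu] <- round(runif(length(neu), 0.05, 0.5), 3)
    sift[neu] <- sample(c("tolerated", NA), length(neu), replace = TRUE)
    polyphen[neu] <- sample(c("benign", NA), length(neu), replace = TRUE)
    cls <- runif(length(neu))
    location[neu[cls < 0.2]] <- sample(c("intronic", "UTR", "intergenic"),
                                       sum(cls < 0.2), replace = TRUE)
    exonic_class[neu] <- ifelse(cls >= 0.2 & cls < 0.5, "synonymous", "nonsynonymous")
    exonic_class[neu[cls < 0.2]] <- "unknown"
    in_segdup[neu] <- runif(length(neu)) < ann_plan$p_segdup_neutral
  }

  dplyr::bind_cols(
    variants[c("chrom", "pos", "ref", "alt")],
    tibble(gene = gene, location_class = location, exonic_class = exonic_class,
           in_cosmic = in_cosmic, dbsnp_id = dbsnp_id, ceu_af = ceu_af,
           sift = sift, polyphen_hdiv = polyphen, in_segdup = in_segdup)
  ) |> dplyr::arrange(.data$chrom, .data$pos)
}

#' @export
print.clonsel_sim <- function(x, ...) {
  cat("<clonsel_sim> ", nrow(x$truth), " variants over ",
      nrow(x$segments), " segments\n", sep = "")
  print(dplyr::count(x$truth, .data$category))
  invisible(x)
}

#' Write a simulated pair to disk
#'
#' Writes the per-sample count TSVs, the annotation TSV, the truth TSV, and
#' the segment grid BED of a [simulate_pair()] result into a directory.
#'
#' @param sim A `clonsel_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_pair <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sensitive = file.path(dir, "sensitive_counts.tsv"),
    resistant = file.path(dir, "resistant_counts.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth_variants.tsv"),
    segments = file.path(dir, "segments.bed")
  )
  readr::write_tsv(sim$sensitive, paths["sensitive"], progress = FALSE)
  readr::write_tsv(sim$resistant, paths["resistant"], progress = FALSE)
  readr::write_tsv(sim$annotations, paths["annotations"], progress = FALSE)
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  write_segment_bed(sim$segments, paths["segments"])
  invisible(paths)
}

#' Default differential-expression plan
#'
#' Plants a small set of up- and down-regulated genes, including one gene
#' down-regulated 17-fold in the resistant sample — the magnitude of the
#' strongest apoptosis-regulator repression seen in resistant lines.
#'
#' @param n_genes Total genes simulated (plan indices must fit).
#' @param n_up,n_down Planted DE genes per direction.
#' @return Tibble with `gene_idx`, `fold_change` (resistant over sensitive;
#'   values below 1 are down-regulation) and `base_mean` (planted baseline
#'   expression, `NA` = drawn with the rest of the transcriptome; the
#'   17-fold gene gets a high baseline so its repression is estimable).
#' @export
default_de_plan <- function(n_genes = 5000, n_up = 15, n_down = 15) {
  n_de <- n_up + n_down
  if (n_de > n_genes) abort("more DE genes than genes")
  up <- if (n_up > 0) seq(3, 10, length.out = n_up) else numeric(0)
  down <- if (n_down > 0) 1 / c(17, seq(3, 10, length.out = n_down))[seq_len(n_down)] else numeric(0)
  plan <- tibble(gene_idx = seq_len(n_de), fold_change = c(up, down),
                 base_mean = NA_real_)
  plan$base_mean[abs(plan$fold_change - 1 / 17) < 1e-12] <- 850
  plan
}

#' Simulate a two-sample gene-count table with planted fold changes
#'
#' Per-gene baseline expression is log-normal; counts are negative-binomial
#' around library-scaled means (`dispersion = 0` gives the Poisson limit,
#' the default: two libraries from the same RNA, differing only by planted
#' fold changes and sampling). Non-DE genes share means across samples up to
#' library-size scaling.
#'
#' @param n_genes Number of genes.
#' @param de_plan Tibble with `gene_idx, fold_change` (resistant/sensitive;
#'   must be positive). `NULL` plants nothing.
#' @param library_sizes Length-2 vector, sensitive and resistant totals
#'   (approximate; realized sums are random).
#' @param dispersion Negative-binomial dispersion `1/size` (0 = Poisson).
#' @param seed Integer seed.
#' @return List of class `clonsel_sim_expr`: `counts` (`gene, count_s,
#'   count_r`) and `truth` (`gene, base_mean, fold_change, planted_de,
#'   direction`).
#' @export
simulate_expression <- function(n_genes = 5000, de_plan = default_de_plan(n_genes),
                                library_sizes = c(2e6, 2e6), dispersion = 0,
                                seed = 1) {
  if (!is.null(de_plan)) {
    de_plan <- as_tibble(de_plan)
    if (any(de_plan$fold_change <= 0)) abort("planted fold changes must be positive")
    if (any(de_plan$gene_idx < 1 | de_plan$gene_idx > n_genes)) {
      abort("de_plan gene indices out of range")
    }
  }
  if (length(library_sizes) != 2 || any(library_sizes <= 0)) {
    abort("library_sizes must be two positive totals")
  }
  withr::with_seed(seed, {
    gene <- sprintf("G%05d", seq_len(n_genes))
    base <- exp(rnorm(n_genes, mean = log(80), sd = 1.2))
    fc <- rep(1, n_genes)
    if (!is.null(de_plan)) {
      fc[de_plan$gene_idx] <- de_plan$fold_change
      if ("base_mean" %in% names(de_plan)) {
        planted <- !is.na(de_plan$base_mean)
        base[de_plan$gene_idx[planted]] <- de_plan$base_mean[planted]
      }
    }
    # means on the per-library scale; baseline is calibrated so the expected
    # library total matches library_sizes[1]
    mu_s <- base / sum(base) * library_sizes[1]
    mu_r <- base * fc / sum(base) * library_sizes[2]
    draw <- function(mu) {
      if (dispersion <= 0) stats::rpois(n_genes, mu)
      else rnbinom(n_genes, size = 1 / dispersion, mu = mu)
    }
    counts <- tibble(gene = gene, count_s = draw(mu_s), count_r = draw(mu_r))
    truth <- tibble(
      gene = gene, base_mean = base, fold_change = fc,
      planted_de = fc != 1,
      direction = dplyr::case_when(fc > 1 ~ "up", fc < 1 ~ "down", TRUE ~ NA_character_)
    )
    structure(list(counts = counts, truth = truth),
              class = "clonsel_sim_expr")
  })
}

#' Simulate overlapping paired-end reads
#'
#' Generates random fragments and reads them in standard FR paired-end mode:
#' R1 is the first `read_length` bases of the fragment, R2 the reverse
#' complement of the last `read_length` bases. Fragments shorter than
#' `2 * read_length` produce overlapping mates with geometric overlap
#' `2 * read_length - fragment_length`; fragments shorter than one read are
#' rejected with a logged skip. Optional substitution errors plant mismatches
#' inside the overlap.
#'
#' @param fragment_lengths Integer vector of fragment lengths; `NULL` draws
#'   `n_pairs` lengths from the library geometry `Normal(175, 70)` (rounded,
#'   floored at 1).
#' @param read_length Read length (default 101).
#' @param n_pairs Number of fragments when `fragment_lengths` is `NULL`.
#' @param substitution_rate Per-base substitution error rate on reads.
#' @param seed Integer seed.
#' @return List of class `clonsel_sim_reads`: `pairs` (tibble `id, seq1,
#'   qual1, seq2, qual2`), `truth` (`id, fragment_length, overlap_len,
#'   fragment_seq`) and `skipped` (lengths rejected as shorter than one
#'   read).
#' @export
simulate_read_pairs <- function(fragment_lengths = NULL, read_length = 101,
                                n_pairs = 200, substitution_rate = 0,
                                seed = 1) {
  if (read_length <= 0) abort("read_length must be positive")
  withr::with_seed(seed, {
    if (is.null(fragment_lengths)) {
      fragment_lengths <- pmax(1, round(rnorm(n_pairs, 175, 70)))
    }
    keep <- fragment_lengths >= read_length
    skipped <- fragment_lengths[!keep]
    if (length(skipped) > 0) {
      inform(sprintf("skipped %d fragment(s) shorter than read length %d",
                     length(skipped), read_length))
    }
    fl <- fragment_lengths[keep]
    bases <- c("A", "C", "G", "T")
    rows <- purrr::imap(fl, function(len, i) {
      frag <- paste(sample(bases, len, replace = TRUE), collapse = "")
      r1 <- substr(frag, 1, read_length)
      r2 <- revcomp(substr(frag, len - read_length + 1, len))
      if (substitution_rate > 0) {
        r1 <- mutate_bases(r1, substitution_rate)
        r2 <- mutate_bases(r2, substitution_rate)
      }
      qual <- paste(rep(intToUtf8(40 + 33), read_length), collapse = "")
      list(
        pair = tibble(id = sprintf("frag%05d", i), seq1 = r1, qual1 = qual,
                      seq2 = r2, qual2 = qual),
        truth = tibble(id = sprintf("frag%05d", i), fragment_length = len,
                       overlap_len = max(0L, as.integer(2 * read_length - len)),
                       fragment_seq = frag)
      )
    })
    structure(
      list(pairs = purrr::map_dfr(rows, "pair"),
           truth = purrr::map_dfr(rows, "truth"),
           skipped = skipped),
      class = "clonsel_sim_reads"
    )
  })
}

mutate_bases <- function(seq, rate) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}
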