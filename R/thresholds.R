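#' Analysis thresholds for the clonal-selection pipeline
#'
#' Bundles every tunable cutoff used across the pipeline stages so they are
#' validated once and shared. Defaults follow the published analysis this
#' package implements: base quality (phred) at least 20, strictly more than 10
#' reads in both samples at a variant position, a 5% population allele
#' frequency ceiling for COSMIC variants, a per-variant Fisher alpha of 1e-3
#' together with a minimum alternative-allele-ratio shift of 0.1 for calling
#' selection, an ancestral-clone floor of 0.30 on both AARs, and differential
#' expression gates of fold change >= 2.5 at BH-adjusted p <= 0.01.
#'
#' @param base_qual_min Minimum base phred quality for a read base to be
#'   counted (documentation of the upstream pileup contract; counts supplied
#'   to this package are assumed already restricted to such bases).
#' @param align_score_min Minimum read alignment score (applied upstream;
#'   recorded here for provenance).
#' @param depth_min_strict Depth filter: inclusion requires strictly more than
#'   this many reads in both samples.
#' @param ceu_af_max Maximum 1000 Genomes CEU alternative-allele frequency for
#'   a COSMIC variant to stay in the analysis.
#' @param fisher_alpha Per-variant significance level of the Fisher exact test
#'   on allele counts.
#' @param delta_aar_min Minimum absolute difference in alternative allele
#'   ratio between the two samples for a selection call.
#' @param ancestral_aar_min Both AARs must exceed this for a non-selected
#'   variant to be assigned to the ancestral clone.
#' @param fc_min Minimum (symmetric) fold change for differential expression.
#' @param adj_p_max Maximum BH-adjusted p-value for differential expression.
#' @param het_min_depth Minimum depth for a site to enter ploidy estimation.
#' @param het_aar_window Open interval of AARs retained as heterozygous for
#'   ploidy estimation.
#'
#' @return An object of class `clonsel_thresholds` (a validated named list).
#' @examples
#' th <- clonsel_thresholds()
#' th$fisher_alpha
#' @export
clonsel_thresholds <- function(base_qual_min = 20,
                               align_score_min = 20,
                               depth_min_strict = 10,
                               ceu_af_max = 0.05,
                               fisher_alpha = 1e-3,
                               delta_aar_min = 0.1,
                               ancestral_aar_min = 0.30,
                               fc_min = 2.5,
                               adj_p_max = 0.01,
                               het_min_depth = 20,
                               het_aar_window = c(0.10, 0.90)) {
  th <- list(
    base_qual_min = base_qual_min,
    align_score_min = align_score_min,
    depth_min_strict = depth_min_strict,
    ceu_af_max = ceu_af_max,
    fisher_alpha = fisher_alpha,
    delta_aar_min = delta_aar_min,
    ancestral_aar_min = ancestral_aar_min,
    fc_min = fc_min,
    adj_p_max = adj_p_max,
    het_min_depth = het_min_depth,
    het_aar_window = het_aar_window
  )
  scalars <- th[setdiff(names(th), "het_aar_window")]
  if (!all(vapply(scalars, function(x) is.numeric(x) && length(x) == 1 && x > 0, logical(1)))) {
    abort("all thresholds must be positive numeric scalars")
  }
  probs <- th[c("ceu_af_max", "fisher_alpha", "delta_aar_min", "ancestral_aar_min", "adj_p_max")]
  if (!all(vapply(probs, function(x) x > 0 && x < 1, logical(1)))) {
    abort("probability-scale thresholds must lie in (0, 1)")
  }
  if (length(het_aar_window) != 2 || het_aar_window[1] >= het_aar_window[2] ||
      het_aar_window[1] < 0 || het_aar_window[2] > 1) {
    abort("`het_aar_window` must be an increasing pair inside [0, 1]")
  }
  structure(th, class = "clonsel_thresholds")
}

#' @export
print.clonsel_thresholds <- function(x, ...) {
  cat("<clonsel_thresholds>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

as_thresholds <- function(x) {
  if (inherits(x, "clonsel_thresholds")) return(x)
  if (is.null(x)) return(clonsel_thresholds())
  do.call(clonsel_thresholds, as.list(x))
}
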