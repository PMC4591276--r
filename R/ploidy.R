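#' Collect heterozygous sites for ploidy estimation
#'
#' Selects, from a merged variant table, the sites in a region that are
#' usable for allelic-imbalance estimation in one sample: covered at
#' `min_depth` or more, with an AAR strictly inside `aar_window` (discarding
#' near-homozygous sites, which carry no imbalance signal).
#'
#' @param merged A merged variant table ([build_merged_table()]).
#' @param sample `"sensitive"` or `"resistant"`.
#' @param region Optional region as a list or one-row data frame with
#'   `chrom`, `start`, `end` (1-based, closed); `NULL` keeps all sites.
#' @param min_depth Minimum site depth (default 20).
#' @param aar_window Open AAR interval retained (default `c(0.10, 0.90)`).
#' @return A tibble with `chrom, pos, depth, alt_count, aar` for the retained
#'   sites (possibly empty).
#' @export
collect_het_sites <- function(merged, sample = c("sensitive", "resistant"),
                              region = NULL, min_depth = 20,
                              aar_window = c(0.10, 0.90)) {
  sample <- match.arg(sample)
  suffix <- if (sample == "sensitive") "_s" else "_r"
  x <- as_tibble(merged)
  x <- tibble(
    chrom = x$chrom, pos = x$pos,
    depth = x[[paste0("depth", suffix)]],
    alt_count = x[[paste0("alt_count", suffix)]],
    aar = x[[paste0("aar", suffix)]]
  )
  if (!is.null(region)) {
    region <- as.list(region)
    x <- dplyr::filter(x, .data$chrom == region$chrom,
                       .data$pos >= region$start, .data$pos <= region$end)
  }
  dplyr::filter(
    x,
    !is.na(.data$depth), .data$depth >= min_depth,
    !is.na(.data$aar),
    .data$aar > aar_window[1], .data$aar < aar_window[2]
  )
}

# Candidate allelic configurations m:(k-m) in lowest terms, canonicalized to
# ratio >= 1/2 (the mirrored likelihood cannot tell m from k-m).
ploidy_grid <- function(k_max = 10) {
  grid <- purrr::map_dfr(2:k_max, function(k) {
    m <- seq.int(ceiling(k / 2), k - 1)
    if (k == 2) m <- 1L
    tibble(k = k, m = m)
  }) |>
    dplyr::filter(mapply(gcd2, .data$m, .data$k) == 1) |>
    dplyr::mutate(ratio = .data$m / .data$k) |>
    dplyr::distinct(.data$ratio, .keep_all = TRUE) |>
    dplyr::arrange(.data$k, abs(.data$ratio - 0.5))
  grid
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Mirrored (beta-)binomial log-likelihood of het-site alt counts at ratio r.
# The mirror mixture reflects unknown phase: either parental haplotype may
# carry the alternative allele.
mirrored_loglik <- function(alt, depth, r, overdispersion = 0) {
  if (overdispersion <= 0) {
    l1 <- dbinom(alt, depth, r, log = TRUE)
    l2 <- dbinom(alt, depth, 1 - r, log = TRUE)
  } else {
    l1 <- dbetabinom_log(alt, depth, r, overdispersion)
    l2 <- dbetabinom_log(alt, depth, 1 - r, overdispersion)
  }
  m <- pmax(l1, l2)
  sum(m + log(0.5 * exp(l1 - m) + 0.5 * exp(l2 - m)))
}

dbetabinom_log <- function(x, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Fit the regional ploidy / allelic-imbalance model
#'
#' Regional "ploidy" here is the total number of parental alleles in a large
#' genomic region. Expression-derived allele ratios at heterozygous sites
#' identify only the allelic configuration `m:(k - m)` — the *ratio* of the
#' two parental copy numbers in lowest terms — so the reported `k` is the
#' smallest ploidy consistent with the estimated ratio, not an absolute copy
#' number (a genuinely tetraploid 2:2 region is indistinguishable from
#' diploid 1:1 and is reported as balanced).
#'
#' For every candidate configuration `r = m/k` (coprime, `2 <= k <= k_max`)
#' the model evaluates the phase-agnostic mirrored likelihood
#' `sum(log(0.5 * Binom(alt | depth, r) + 0.5 * Binom(alt | depth, 1 - r)))`
#' and selects the candidate maximizing a penalized score with two terms:
#' a BIC term (the balanced configuration `1/2` has no free ratio
#' parameter; unbalanced candidates pay one) and a description-length term
#' `log(k) + log(n_m(k))` (`n_m(k)` = number of canonical coprime
#' numerators for denominator `k`). The latter corrects the multiplicity
#' bias of the candidate grid: large denominators contribute more, and more
#' closely spaced, ratios, so an unpenalized maximum likelihood drifts
#' toward them. Ties go to the smaller `k`, then to the ratio closer to 1/2.
#'
#' @param sites Het-site tibble from [collect_het_sites()] (needs
#'   `alt_count`, `depth`).
#' @param k_max Largest ploidy considered (default 10).
#' @param min_sites Minimum number of sites to attempt a call (default 20);
#'   fewer yields a no-call fit.
#' @param overdispersion Optional beta-binomial overdispersion `rho` in
#'   (0, 1); 0 (default) uses the plain binomial.
#' @return A `ploidy_fit` object with the candidate grid, the selected
#'   configuration (`k`, `m`, `balanced`, `label`), `loglik` and `n_sites`.
#' @examples
#' set.seed(1)
#' sites <- tibble::tibble(depth = rep(200, 100),
#'                         alt_count = rbinom(100, 200, 0.75))
#' fit_region_ploidy(sites)
#' @export
fit_region_ploidy <- function(sites, k_max = 10, min_sites = 20,
                              overdispersion = 0) {
  sites <- as_tibble(sites)
  n <- nrow(sites)
  if (n < min_sites) {
    return(new_ploidy_fit(NULL, k = NA_integer_, m = NA_integer_,
                          balanced = NA, loglik = NA_real_, n_sites = n,
                          no_call = TRUE, sites = sites))
  }
  grid <- ploidy_grid(k_max) |>
    dplyr::add_count(.data$k, name = "n_numerators") |>
    dplyr::mutate(
      df = ifelse(.data$ratio == 0.5, 0, 1),
      complexity = log(.data$k) + log(.data$n_numerators),
      loglik = purrr::map_dbl(.data$ratio, function(r) {
        mirrored_loglik(sites$alt_count, sites$depth, r, overdispersion)
      }),
      score = .data$loglik - 0.5 * .data$df * log(n) - .data$complexity
    )
  # grid is ordered by (k, |r - 1/2|); the first score within tolerance of
  # the maximum implements the tie-break
  best <- which(grid$score >= max(grid$score) - 1e-9)[1]
  new_ploidy_fit(grid, k = grid$k[best], m = grid$m[best],
                 balanced = grid$ratio[best] == 0.5,
                 loglik = grid$loglik[best], n_sites = n, no_call = FALSE,
                 sites = sites)
}

new_ploidy_fit <- function(grid, k, m, balanced, loglik, n_sites, no_call,
                           sites) {
  structure(
    list(grid = grid, k = k, m = m, balanced = balanced,
         label = ploidy_label(k, balanced, no_call),
         loglik = loglik, n_sites = n_sites, no_call = no_call,
         sites = sites),
    class = "ploidy_fit"
  )
}

#' Human-readable ploidy label
#'
#' Maps a fitted configuration to the conventional label: `"-"` for absence
#' of allelic imbalance (balanced), `"tri-ploidy"` ... `"deca-ploidy"` for an
#' unbalanced call of `k` total alleles, `NA` for no call.
#'
#' @param k Integer ploidy (vectorized).
#' @param balanced Logical: best configuration is 1:1.
#' @param no_call Logical: too few sites to call.
#' @return Character vector of labels.
#' @export
ploidy_label <- function(k, balanced, no_call = FALSE) {
  prefixes <- c("di", "tri", "tetra", "penta", "hexa", "hepta", "octa",
                "nona", "deca")
  out <- ifelse(balanced, "-", paste0(prefixes[pmax(k, 2) - 1], "-ploidy"))
  out[no_call | is.na(k) | is.na(balanced)] <- NA_character_
  out[no_call] <- NA_character_
  out
}

#' @export
print.ploidy_fit <- function(x, ...) {
  if (x$no_call) {
    cat("<ploidy_fit> no call (", x$n_sites, " sites)\n", sep = "")
  } else {
    cat(sprintf("<ploidy_fit> k=%d m=%d (%s), loglik=%.2f, %d sites\n",
                x$k, x$m, x$label, x$loglik, x$n_sites))
  }
  invisible(x)
}

#' Tidy the ploidy candidate grid
#'
#' @param x A `ploidy_fit` object.
#' @param ... Unused.
#' @return For `tidy()`, the full candidate grid (`k`, `m`, `ratio`,
#'   `loglik`, `df`, `score`); for `glance()`, a one-row summary of the
#'   selected configuration.
#' @method tidy ploidy_fit
#' @export
tidy.ploidy_fit <- function(x, ...) {
  if (is.null(x$grid)) return(tibble())
  x$grid
}

#' @rdname tidy.ploidy_fit
#' @method glance ploidy_fit
#' @export
glance.ploidy_fit <- function(x, ...) {
  tibble(k = x$k, m = x$m, balanced = x$balanced, label = x$label,
         loglik = x$loglik, n_sites = x$n_sites, no_call = x$no_call)
}

#' @rdname tidy.ploidy_fit
#' @param object A `ploidy_fit` object.
#' @method autoplot ploidy_fit
#' @export
autoplot.ploidy_fit <- function(object, ...) {
  sites <- as_tibble(object$sites)
  if (!"aar" %in% names(sites)) sites$aar <- sites$alt_count / sites$depth
  p <- ggplot2::ggplot(sites, ggplot2::aes(x = .data$aar)) +
    ggplot2::geom_histogram(binwidth = 0.02, fill = "grey70", colour = "grey40") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "heterozygous-site AAR", y = "sites") +
    ggplot2::theme_minimal()
  if (!object$no_call) {
    r <- object$m / object$k
    p <- p + ggplot2::geom_vline(xintercept = c(r, 1 - r),
                                 colour = "#c0392b", linetype = "dashed")
  }
  p
}

#' Call ploidy segments over a region grid
#'
#' Fits the regional allelic-imbalance model ([fit_region_ploidy()]) in each
#' region of a fixed segment grid, for one sample of a merged variant table.
#'
#' @param merged Merged variant table.
#' @param segments Region grid: tibble with `chrom, start, end` (1-based,
#'   closed; see [read_segment_bed()]).
#' @param sample `"sensitive"` or `"resistant"`.
#' @param thresholds A [clonsel_thresholds()] (supplies `het_min_depth` and
#'   `het_aar_window`) or `NULL`.
#' @param k_max,min_sites,overdispersion Passed to [fit_region_ploidy()].
#' @return A tibble with one row per region: `chrom, start, end, sample,
#'   ploidy_k, alt_copies_m, balanced, label, loglik, n_sites`.
#' @export
call_ploidy_segments <- function(merged, segments,
                                 sample = c("sensitive", "resistant"),
                                 thresholds = NULL, k_max = 10,
                                 min_sites = 20, overdispersion = 0) {
  sample <- match.arg(sample)
  th <- as_thresholds(thresholds)
  segments <- as_tibble(segments)
  purrr::pmap_dfr(
    segments[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sites <- collect_het_sites(
        merged, sample = sample,
        region = list(chrom = chrom, start = start, end = end),
        min_depth = th$het_min_depth, aar_window = th$het_aar_window
      )
      fit <- fit_region_ploidy(sites, k_max = k_max, min_sites = min_sites,
                               overdispersion = overdispersion)
      tibble(chrom = chrom, start = start, end = end, sample = sample,
             ploidy_k = fit$k, alt_copies_m = fit$m, balanced = fit$balanced,
             label = fit$label, loglik = fit$loglik, n_sites = fit$n_sites)
    }
  )
}

#' Compare sensitive and resistant segment calls
#'
#' Emits the regions whose allelic-imbalance call differs between the two
#' samples — the layout of a ploidy-variation table, with `"-"` denoting
#' absence of allelic imbalance.
#'
#' @param sensitive_segments,resistant_segments Segment-call tibbles from
#'   [call_ploidy_segments()], on the same region grid.
#' @return A tibble of differing regions: `chrom, start, end, sensitive,
#'   resistant` (labels).
#' @export
compare_segments <- function(sensitive_segments, resistant_segments) {
  key <- c("chrom", "start", "end")
  s <- as_tibble(sensitive_segments)
  r <- as_tibble(resistant_segments)
  only_s <- dplyr::anti_join(s[key], r[key], by = key)
  only_r <- dplyr::anti_join(r[key], s[key], by = key)
  if (nrow(only_s) > 0 || nrow(only_r) > 0) {
    bad <- dplyr::bind_rows(only_s, only_r)
    abort(paste0("segment grids differ; unmatched region(s): ",
                 paste(head(paste0(bad$chrom, ":", bad$start, "-", bad$end), 10),
                       collapse = ", ")))
  }
  dplyr::inner_join(
    dplyr::select(s, dplyr::all_of(key), sensitive = "label"),
    dplyr::select(r, dplyr::all_of(key), resistant = "label"),
    by = key
  ) |>
    dplyr::filter(
      dplyr::coalesce(.data$sensitive, "NA") != dplyr::coalesce(.data$resistant, "NA")
    )
}

#' Read a segment grid from BED
#'
#' BED is 0-based, half-open on disk; regions are converted to the package's
#' 1-based, fully closed convention.
#'
#' @param path BED file (3+ columns, no header).
#' @return Tibble with `chrom, start, end` (1-based closed) and `name` if a
#'   fourth column is present.
#' @export
read_segment_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE,
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 3) abort("BED needs at least 3 columns")
  out <- tibble(
    chrom = x[[1]],
    start = as.numeric(x[[2]]) + 1,
    end = as.numeric(x[[3]])
  )
  if (ncol(x) >= 4) out$name <- x[[4]]
  out
}

#' Write a segment grid as BED
#'
#' @param segments Tibble with `chrom, start, end` (1-based closed).
#' @param path Output path.
#' @export
write_segment_bed <- function(segments, path) {
  x <- as_tibble(segments)
  bed <- tibble(chrom = x$chrom, start = format(x$start - 1, scientific = FALSE, trim = TRUE),
                end = format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) bed$name <- x$name
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
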