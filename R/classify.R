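#' Classify variants as selected, ancestral, or unclassified
#'
#' The core clonal-selection call. For every variant with counts in both
#' samples, the sensitive-vs-resistant allele counts form a 2x2 table
#' `[[ref_s, alt_s], [ref_r, alt_r]]` tested with the two-sided Fisher exact
#' test ([fisher_exact_two_sided()]). With `delta_aar = aar_r - aar_s`:
#'
#' * `selected_up`: `fisher_p <= fisher_alpha` and `delta_aar >=
#'   delta_aar_min` — the variant's clone expanded under treatment;
#' * `selected_down`: `fisher_p <= fisher_alpha` and `delta_aar <=
#'   -delta_aar_min` — the clone was depleted;
#' * `ancestral`: not selected, and AAR above `ancestral_aar_min` in *both*
#'   samples — a variant of the ancestral tumor clone present before
#'   treatment;
#' * `unclassified`: everything else.
#'
#' The categories are mutually exclusive and exhaustive; swapping the two
#' samples swaps `selected_up` and `selected_down`, negates `delta_aar` and
#' leaves `fisher_p` unchanged.
#'
#' @param variants A tibble with columns `ref_count_s, alt_count_s,
#'   ref_count_r, alt_count_r` (typically the output of [filter_variants()]).
#'   Rows with missing counts in either sample are an error: the depth filter
#'   should have removed them.
#' @param thresholds A [clonsel_thresholds()] object or `NULL` for defaults.
#' @return A `clonal_calls` tibble: the input plus `aar_s`, `aar_r`,
#'   `delta_aar`, `fisher_p` and `category`.
#' @examples
#' x <- tibble::tibble(ref_count_s = c(100, 20, 95), alt_count_s = c(0, 20, 5),
#'                     ref_count_r = c(65, 20, 95), alt_count_r = c(35, 20, 5))
#' classify_variants(x)
#' @export
classify_variants <- function(variants, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  x <- as_tibble(variants)
  need <- c("ref_count_s", "alt_count_s", "ref_count_r", "alt_count_r")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing count columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(x[need])) {
    abort("missing counts in one sample; apply the depth filter before classifying")
  }
  x <- x |>
    dplyr::mutate(
      aar_s = aar(.data$ref_count_s, .data$alt_count_s),
      aar_r = aar(.data$ref_count_r, .data$alt_count_r)
    )
  if (anyNA(x$aar_s) || anyNA(x$aar_r)) {
    abort("AAR undefined (zero depth) in one sample; filter before classifying")
  }
  x <- x |>
    dplyr::mutate(
      delta_aar = .data$aar_r - .data$aar_s,
      fisher_p = fisher_exact_two_sided(
        .data$ref_count_s, .data$alt_count_s,
        .data$ref_count_r, .data$alt_count_r
      ),
      category = dplyr::case_when(
        fisher_p <= th$fisher_alpha & delta_aar >= th$delta_aar_min ~ "selected_up",
        fisher_p <= th$fisher_alpha & delta_aar <= -th$delta_aar_min ~ "selected_down",
        aar_s > th$ancestral_aar_min & aar_r > th$ancestral_aar_min ~ "ancestral",
        TRUE ~ "unclassified"
      )
    )
  new_clonal_calls(x, th)
}

new_clonal_calls <- function(x, thresholds) {
  structure(x, thresholds = thresholds,
            class = c("clonal_calls", class(tibble())))
}

#' Summarize clonal-selection calls
#'
#' Per-category counts plus the per-direction variant lists, sorted by the
#' magnitude of the AAR shift — the layout of a published selected-mutation
#' table (gene, label, sensitive AF, resistant AF).
#'
#' @param calls A `clonal_calls` tibble from [classify_variants()].
#' @return A list with `counts` (tibble of category/n over all four
#'   categories, in fixed order) and `selected` (tibble of `selected_up` /
#'   `selected_down` rows sorted by decreasing `abs(delta_aar)`).
#' @export
summarize_calls <- function(calls) {
  categories <- c("selected_up", "selected_down", "ancestral", "unclassified")
  counts <- tibble(category = categories) |>
    dplyr::left_join(dplyr::count(as_tibble(calls), .data$category), by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  id_cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "label"), names(calls))
  selected <- as_tibble(calls) |>
    dplyr::filter(.data$category %in% c("selected_up", "selected_down")) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta_aar))) |>
    dplyr::select(dplyr::all_of(id_cols), "aar_s", "aar_r",
                  "delta_aar", "fisher_p", "category")
  list(counts = counts, selected = selected)
}

#' @export
print.clonal_calls <- function(x, ...) {
  counts <- summarize_calls(x)$counts
  cat("<clonal_calls> ", nrow(x), " variants: ",
      paste(sprintf("%s=%d", counts$category, counts$n), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}

#' Tidy a clonal-calls table
#'
#' @param x A `clonal_calls` object.
#' @param ... Unused.
#' @return For `tidy()`, one row per variant with the key, AARs, shift,
#'   Fisher p and category; for `glance()`, a one-row summary of category
#'   counts and the thresholds used.
#' @method tidy clonal_calls
#' @export
tidy.clonal_calls <- function(x, ...) {
  id_cols <- intersect(c("chrom", "pos", "ref", "alt", "gene"), names(x))
  as_tibble(x)[c(id_cols, "aar_s", "aar_r", "delta_aar", "fisher_p", "category")]
}

#' @rdname tidy.clonal_calls
#' @method glance clonal_calls
#' @export
glance.clonal_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  counts <- summarize_calls(x)$counts
  tibble(
    n_variants = nrow(x),
    n_selected_up = counts$n[counts$category == "selected_up"],
    n_selected_down = counts$n[counts$category == "selected_down"],
    n_ancestral = counts$n[counts$category == "ancestral"],
    n_unclassified = counts$n[counts$category == "unclassified"],
    fisher_alpha = th$fisher_alpha,
    delta_aar_min = th$delta_aar_min,
    ancestral_aar_min = th$ancestral_aar_min
  )
}

#' AAR scatter of clonal-selection calls
#'
#' Sensitive-sample AAR against resistant-sample AAR, one point per variant,
#' colored by call category — the standard visual for clonal selection
#' between paired samples (de-novo expanding variants sit on the left edge,
#' ancestral variants near the diagonal).
#'
#' @param object A `clonal_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clonal_calls
#' @export
autoplot.clonal_calls <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$aar_s, y = .data$aar_r,
                               colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1) * th$delta_aar_min,
                         linetype = "dashed", colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      selected_up = "#c0392b", selected_down = "#2980b9",
      ancestral = "grey40", unclassified = "grey75"
    )) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "AAR (sensitive)", y = "AAR (resistant)",
                  colour = "category") +
    ggplot2::theme_minimal()
}
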