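#' Exact conditional binomial test for one gene between two libraries
#'
#' Per-gene differential-expression statistic for a two-sample comparison
#' without replicates. Conditional on the gene's total count
#' `n = count_s + count_r`, the sensitive-sample count is
#' `Binomial(n, lib_s / (lib_s + lib_r))` under the null of equal relative
#' expression. The two-sided p-value sums the probabilities of all outcomes
#' no more probable than the observed one (relative tie tolerance 1e-7);
#' `p = 1` when the gene has no reads at all.
#'
#' @param count_s,count_r Non-negative read counts (vectorized).
#' @param lib_s,lib_r Positive library sizes.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' de_test(5, 5, 1e6, 1e6)     # 1: the modal outcome
#' de_test(0, 100, 1e6, 1e6)   # 2 * (1/2)^100
#' @export
de_test <- function(count_s, count_r, lib_s, lib_r) {
  n_genes <- max(length(count_s), length(count_r))
  count_s <- rep_len(count_s, n_genes); count_r <- rep_len(count_r, n_genes)
  lib_s <- rep_len(lib_s, n_genes); lib_r <- rep_len(lib_r, n_genes)
  if (any(lib_s <= 0) || any(lib_r <= 0)) abort("library sizes must be positive")
  if (anyNA(count_s) || anyNA(count_r) || any(count_s < 0) || any(count_r < 0)) {
    abort("counts must be non-negative and not NA")
  }
  vapply(seq_len(n_genes), function(i) {
    n <- count_s[i] + count_r[i]
    if (n == 0) return(1)
    pi0 <- lib_s[i] / (lib_s[i] + lib_r[i])
    probs <- dbinom(0:n, n, pi0)
    p <- sum(probs[probs <= probs[count_s[i] + 1] * (1 + 1e-7)])
    min(p, 1)
  }, numeric(1))
}

#' Call differentially expressed genes between two samples
#'
#' Tests every gene with [de_test()], adjusts p-values with
#' Benjamini-Hochberg ([stats::p.adjust()]), and flags genes passing both the
#' fold-change and adjusted-p gates. The fold change is computed on the
#' library-normalized scale with a 0.5 pseudocount,
#' `((count_r + 0.5) / lib_r) / ((count_s + 0.5) / lib_s)`, and reported
#' symmetrically: `fold_change` is the larger of the ratio and its inverse,
#' with `direction` (`"up"`/`"down"`, resistant relative to sensitive)
#' carried separately, so a single `fc_min` gate covers both directions.
#' Genes with zero counts in both samples are excluded from testing (and
#' from the BH denominator).
#'
#' @param count_table Tibble with columns `gene, count_s, count_r` (one row
#'   per gene; duplicate gene symbols are an error).
#' @param thresholds A [clonsel_thresholds()] object or `NULL` (gates
#'   `fc_min`, `adj_p_max`).
#' @param lib_s,lib_r Library sizes; default column sums.
#' @return A `dge_result` tibble: input plus `ratio` (signed normalized
#'   ratio), `fold_change`, `direction`, `p_raw`, `p_adj`, `is_de`.
#' @examples
#' counts <- tibble::tibble(gene = c("BMF", "ACTB"),
#'                          count_s = c(850, 5000), count_r = c(50, 5000))
#' call_de(counts, lib_s = 1e6, lib_r = 1e6)
#' @export
call_de <- function(count_table, thresholds = NULL, lib_s = NULL, lib_r = NULL) {
  th <- as_thresholds(thresholds)
  x <- as_tibble(count_table)
  need <- c("gene", "count_s", "count_r")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$gene)) abort("duplicate gene symbols in count table")
  lib_s <- lib_s %||% sum(x$count_s)
  lib_r <- lib_r %||% sum(x$count_r)
  if (lib_s <= 0 || lib_r <= 0) abort("library sizes must be positive")

  x <- x |>
    dplyr::mutate(
      tested = .data$count_s + .data$count_r > 0,
      ratio = ((.data$count_r + 0.5) / lib_r) / ((.data$count_s + 0.5) / lib_s),
      fold_change = pmax(.data$ratio, 1 / .data$ratio),
      direction = ifelse(.data$ratio >= 1, "up", "down"),
      p_raw = NA_real_, p_adj = NA_real_
    )
  idx <- which(x$tested)
  if (length(idx) > 0) {
    x$p_raw[idx] <- de_test(x$count_s[idx], x$count_r[idx], lib_s, lib_r)
    x$p_adj[idx] <- p.adjust(x$p_raw[idx], method = "BH")
  }
  x <- x |>
    dplyr::mutate(
      is_de = .data$tested & !is.na(.data$p_adj) &
        .data$fold_change >= th$fc_min & .data$p_adj <= th$adj_p_max
    )
  structure(x, lib_s = lib_s, lib_r = lib_r, thresholds = th,
            class = c("dge_result", class(tibble())))
}

#' @export
print.dge_result <- function(x, ...) {
  cat("<dge_result> ", nrow(x), " genes, ", sum(x$is_de), " DE (",
      sum(x$is_de & x$direction == "up"), " up, ",
      sum(x$is_de & x$direction == "down"), " down)\n", sep = "")
  NextMethod()
}

#' Tidy a differential-expression result
#'
#' @param x A `dge_result` from [call_de()].
#' @param ... Unused.
#' @return For `tidy()`, the per-gene table; for `glance()`, a one-row
#'   summary (gene and DE counts, library sizes, gates).
#' @method tidy dge_result
#' @export
tidy.dge_result <- function(x, ...) {
  as_tibble(x)[c("gene", "count_s", "count_r", "ratio", "fold_change",
                 "direction", "p_raw", "p_adj", "is_de")]
}

#' @rdname tidy.dge_result
#' @method glance dge_result
#' @export
glance.dge_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_genes = nrow(x), n_tested = sum(x$tested),
    n_de = sum(x$is_de),
    n_de_up = sum(x$is_de & x$direction == "up"),
    n_de_down = sum(x$is_de & x$direction == "down"),
    lib_s = attr(x, "lib_s"), lib_r = attr(x, "lib_r"),
    fc_min = th$fc_min, adj_p_max = th$adj_p_max
  )
}

#' @rdname tidy.dge_result
#' @param object A `dge_result`.
#' @method autoplot dge_result
#' @export
autoplot.dge_result <- function(object, ...) {
  th <- attr(object, "thresholds")
  x <- as_tibble(object) |> dplyr::filter(.data$tested)
  ggplot2::ggplot(x, ggplot2::aes(x = log2(.data$ratio),
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(th$fc_min),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = -log10(th$adj_p_max),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    ggplot2::labs(x = "log2 normalized ratio (resistant / sensitive)",
                  y = "-log10 adjusted p", colour = "DE") +
    ggplot2::theme_minimal()
}

#' Read a gene-count table
#'
#' TSV dialect: header `gene count_sensitive count_resistant` (or
#' `gene count_s count_r`).
#'
#' @param path File path.
#' @return Tibble with `gene, count_s, count_r`.
#' @export
read_gene_counts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (all(c("count_sensitive", "count_resistant") %in% names(x))) {
    x <- dplyr::rename(x, count_s = "count_sensitive", count_r = "count_resistant")
  }
  if (!all(c("gene", "count_s", "count_r") %in% names(x))) {
    abort("gene-count table needs columns gene, count_sensitive, count_resistant")
  }
  x[c("gene", "count_s", "count_r")]
}
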