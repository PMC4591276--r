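#' Load and validate a pipeline run configuration
#'
#' The run configuration is a YAML file (or an equivalent nested list) with
#' sections `inputs` (paths: `sensitive_counts`, `resistant_counts`,
#' `annotations`; optionally `segments_bed` and `gene_counts`),
#' `thresholds` (any subset of [clonsel_thresholds()] fields), and top-level
#' `output_dir`, `seed` and `cosmic_match`. Every referenced input path must
#' exist.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return A validated list of class `clonsel_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML path or a list")
  inputs <- config$inputs %||% list()
  required <- c("sensitive_counts", "resistant_counts", "annotations")
  missing_in <- setdiff(required, names(inputs))
  if (length(missing_in) > 0) {
    abort(paste0("config missing inputs: ", paste(missing_in, collapse = ", ")))
  }
  for (nm in names(inputs)) {
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]])) {
      abort(paste0("input path does not exist: ", nm, " = ", inputs[[nm]]))
    }
  }
  th <- do.call(clonsel_thresholds, config$thresholds %||% list())
  structure(
    list(
      inputs = inputs,
      thresholds = th,
      output_dir = config$output_dir %||% ".",
      seed = config$seed %||% 1L,
      cosmic_match = config$cosmic_match %||% "allele"
    ),
    class = "clonsel_config"
  )
}

stage <- function(name, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    }),
    message = function(m) m
  )
}

log_counts <- function(stage_name, ...) {
  kv <- c(...)
  inform(paste0("[", stage_name, "] ",
                paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

#' Run the clonal-selection pipeline end to end
#'
#' Executes the stages on one sensitive/resistant pair: load allele counts,
#' build the merged variant table, apply the annotation inclusion filter,
#' classify variants by clonal selection; independently, call ploidy
#' segments (when a segment grid is configured) and differential expression
#' (when a gene-count table is configured). All stage outputs are written
#' under `output_dir` as TSV, together with a human-readable `report.txt`
#' and a machine-readable `summary.yaml`. Record counts in and out of every
#' stage are logged to standard error.
#'
#' @param config A [load_run_config()] result, a YAML path, or a list.
#' @return The run report (list of class `clonsel_report`), invisibly
#'   containing all stage summaries and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "clonsel_config")) config else load_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds

  sens <- stage("variants", load_sample_counts(cfg$inputs$sensitive_counts))
  resi <- stage("variants", load_sample_counts(cfg$inputs$resistant_counts))
  log_counts("variants", loaded_sensitive = nrow(sens), loaded_resistant = nrow(resi))
  merged <- stage("variants", build_merged_table(sens, resi))
  log_counts("variants", merged_records = nrow(merged))
  write_merged_table(merged, file.path(cfg$output_dir, "merged_table.tsv"))

  ann <- stage("selection_filter", read_annotations(cfg$inputs$annotations))
  audit <- stage("selection_filter",
                 variant_inclusion(merged, ann, th, cfg$cosmic_match))
  included <- dplyr::filter(audit, .data$include)
  fcounts <- c(total = nrow(audit), unannotated = sum(!audit$annotated),
               excluded = sum(audit$annotated & !audit$include),
               included = nrow(included))
  log_counts("selection_filter", records_in = fcounts[["total"]],
             unannotated = fcounts[["unannotated"]],
             excluded = fcounts[["excluded"]],
             included = fcounts[["included"]])
  write_inclusion_audit(audit, file.path(cfg$output_dir, "inclusion_audit.tsv"))

  calls <- stage("clonal_selection", classify_variants(included, th))
  call_summary <- summarize_calls(calls)
  log_counts("clonal_selection",
             setNames(call_summary$counts$n, call_summary$counts$category))
  readr::write_tsv(tidy(calls), file.path(cfg$output_dir, "clonal_calls.tsv"),
                   progress = FALSE)
  readr::write_tsv(call_summary$selected,
                   file.path(cfg$output_dir, "selected_variants.tsv"),
                   progress = FALSE)

  ploidy_out <- NULL
  if (!is.null(cfg$inputs$segments_bed)) {
    segs <- stage("ploidy", read_segment_bed(cfg$inputs$segments_bed))
    seg_s <- stage("ploidy", call_ploidy_segments(merged, segs, "sensitive", th))
    seg_r <- stage("ploidy", call_ploidy_segments(merged, segs, "resistant", th))
    diffs <- stage("ploidy", compare_segments(seg_s, seg_r))
    log_counts("ploidy", segments = nrow(segs), differing = nrow(diffs))
    readr::write_tsv(seg_s, file.path(cfg$output_dir, "ploidy_sensitive.tsv"),
                     progress = FALSE)
    readr::write_tsv(seg_r, file.path(cfg$output_dir, "ploidy_resistant.tsv"),
                     progress = FALSE)
    readr::write_tsv(diffs, file.path(cfg$output_dir, "ploidy_differences.tsv"),
                     progress = FALSE)
    ploidy_out <- list(sensitive = seg_s, resistant = seg_r, differences = diffs)
  }

  dge_out <- NULL
  if (!is.null(cfg$inputs$gene_counts)) {
    counts <- stage("expression", read_gene_counts(cfg$inputs$gene_counts))
    dge <- stage("expression", call_de(counts, th))
    log_counts("expression", genes = nrow(dge), de = sum(dge$is_de))
    readr::write_tsv(tidy(dge), file.path(cfg$output_dir, "dge.tsv"),
                     progress = FALSE)
    de_only <- tidy(dge) |>
      dplyr::filter(.data$is_de) |>
      dplyr::arrange(dplyr::desc(abs(log(.data$ratio))))
    readr::write_tsv(de_only, file.path(cfg$output_dir, "de_genes.tsv"),
                     progress = FALSE)
    dge_out <- dge
  }

  report <- make_report(list(
    filter_counts = fcounts,
    calls = calls,
    call_summary = call_summary,
    ploidy = ploidy_out,
    dge = dge_out
  ))
  writeLines(report$text, file.path(cfg$output_dir, "report.txt"))
  yaml::write_yaml(report$summary, file.path(cfg$output_dir, "summary.yaml"))
  invisible(structure(c(report, list(output_dir = cfg$output_dir)),
                      class = "clonsel_report"))
}

#' Assemble the pipeline report
#'
#' Builds the human-readable text report and the machine-readable summary
#' from stage outputs: variant counts at each filter step, clonal-selection
#' category counts, the selected-variant table (gene, label, sensitive AF,
#' resistant AF), ploidy differences, and DE counts. Output ordering is
#' deterministic.
#'
#' @param stage_outputs List with elements `filter_counts`, `calls`,
#'   `call_summary`, and optionally `ploidy` and `dge` (as produced inside
#'   [run_pipeline()]).
#' @return List with `text` (character lines) and `summary` (nested list of
#'   counts).
#' @export
make_report <- function(stage_outputs) {
  so <- stage_outputs
  txt <- c("clonal selection pipeline report",
           "================================", "")
  fc <- so$filter_counts
  txt <- c(txt, "variant filtering:",
           sprintf("  %-12s %d", names(fc), unname(fc)), "")
  counts <- so$call_summary$counts
  txt <- c(txt, "clonal selection calls:",
           sprintf("  %-14s %d", counts$category, counts$n), "")
  sel <- so$call_summary$selected
  txt <- c(txt, sprintf("selected variants (%d):", nrow(sel)))
  if (nrow(sel) > 0) {
    gene_col <- if ("gene" %in% names(sel)) sel$gene else rep("?", nrow(sel))
    txt <- c(txt, sprintf("  %-12s AF %0.2f -> %0.2f  p=%.3g  %s",
                          gene_col, sel$aar_s, sel$aar_r, sel$fisher_p,
                          sel$category))
  }
  txt <- c(txt, "")
  summary <- list(
    filter = as.list(fc),
    categories = as.list(setNames(counts$n, counts$category))
  )
  if (!is.null(so$ploidy)) {
    d <- so$ploidy$differences
    txt <- c(txt, sprintf("ploidy differences (%d):", nrow(d)))
    if (nrow(d) > 0) {
      txt <- c(txt, sprintf("  %s:%d-%d  sensitive: %s  resistant: %s",
                            d$chrom, d$start, d$end,
                            ifelse(is.na(d$sensitive), "no call", d$sensitive),
                            ifelse(is.na(d$resistant), "no call", d$resistant)))
    }
    txt <- c(txt, "")
    summary$ploidy <- list(segments = nrow(so$ploidy$sensitive),
                           differing = nrow(d))
  }
  if (!is.null(so$dge)) {
    g <- glance(so$dge)
    txt <- c(txt, sprintf("differential expression: %d genes tested, %d DE (%d up, %d down)",
                          g$n_tested, g$n_de, g$n_de_up, g$n_de_down), "")
    summary$dge <- list(tested = g$n_tested, de = g$n_de,
                        de_up = g$n_de_up, de_down = g$n_de_down)
  }
  list(text = txt, summary = summary)
}

#' @export
print.clonsel_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Variants qualifying under the AAR-shift rule
#'
#' Applies the minimum AAR-shift rule to a table of per-variant sensitive
#' and resistant allele fractions — for example a published selected-mutation
#' table — returning the rows with `|af_resistant - af_sensitive| >=
#' delta_aar_min`. This is the effect-size half of the selection call,
#' usable when only allele fractions (not counts) are available.
#'
#' @param af_table Tibble with numeric columns `af_sensitive`,
#'   `af_resistant`.
#' @param delta_aar_min Minimum absolute AAR shift (default 0.1).
#' @return The qualifying rows, with a `delta_aar` column.
#' @examples
#' path <- system.file("extdata", "selected_mutations_af.tsv", package = "clonsel")
#' tab <- readr::read_tsv(path, show_col_types = FALSE)
#' dplyr::count(qualifying_shifts(tab), cell_line)
#' @export
qualifying_shifts <- function(af_table, delta_aar_min = 0.1) {
  x <- as_tibble(af_table)
  if (!all(c("af_sensitive", "af_resistant") %in% names(x))) {
    abort("af_table needs columns af_sensitive and af_resistant")
  }
  x |>
    dplyr::mutate(delta_aar = .data$af_resistant - .data$af_sensitive) |>
    dplyr::filter(abs(.data$delta_aar) >= delta_aar_min)
}
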