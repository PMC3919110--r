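# File-level pipeline: read inputs, fit the differential correlation
# analysis, write the report files. Reports are staged in a temporary
# directory and moved into place only on success, so a failing run leaves no
# partial reports behind. All numeric columns carrying correlations are
# written with 17 significant digits so that stage-wise runs reproduce the
# monolithic pipeline byte for byte.

.fmt_num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))

#' Write per-pair correlation results as TSV
#'
#' @param results data.frame from [correlate_pairs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_correlations <- function(results, path) {
  out <- results
  out$r <- .fmt_num(out$r)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-pair correlation results written by [write_pair_correlations()]
#'
#' @param path file path.
#' @return data.frame with the [correlate_pairs()] columns; `r` is numeric
#'   and round-trips exactly.
#' @export
read_pair_correlations <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "")
  df$n_total <- as.integer(df$n_total)
  df$n_used <- as.integer(df$n_used)
  df$r <- suppressWarnings(as.numeric(df$r))
  df
}

#' Write the differential-pair table as TSV
#'
#' @param deltas data.frame from [select_differential()] (optionally with
#'   gene/pathway columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_differential_pairs <- function(deltas, path) {
  out <- deltas
  for (col in intersect(c("r_ref", "r_test", "cor_dif", "cor_dif_gene"),
                        names(out)))
    out[[col]] <- .fmt_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-condition classification counts as TSV
#'
#' One row per condition with its sample count and the number of coexpressed
#' (`r > threshold`), reverse (`r < -threshold`), unrelated and undefined
#' pairs, plus the number of selected differential pairs.
#'
#' @param fit a `diffcorr` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_class_counts <- function(fit, path) {
  counts <- do.call(rbind, fit$counts)
  df <- data.frame(condition = rownames(counts),
                   n_samples = fit$n_samples[rownames(counts)],
                   counts,
                   n_differential = nrow(fit$selected),
                   row.names = NULL, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from files to reports
#'
#' Reads the expression matrix, design, annotation and KGML pathway files,
#' fits [diffcorr()], and writes into `out_dir`:
#' `pair_correlations_<condition>.tsv` (one per condition),
#' `differential_pairs.tsv`, `pathway_report.tsv`, `class_counts.tsv` and
#' `run_metadata.json` (configuration echo, counts and selection statistics).
#' Reports are staged and moved atomically; on any failure no partial report
#' is left in `out_dir`.
#'
#' @param matrix_path expression matrix file.
#' @param design_path sample design file.
#' @param reference reference condition label.
#' @param out_dir output directory (created if needed).
#' @param annotation_path optional probe annotation file (required with
#'   `kgml_dir`).
#' @param kgml_dir optional directory of KGML `.xml` files; when absent the
#'   analysis runs over all probe pairs.
#' @param dialect expression matrix dialect, see [read_expression_matrix()].
#' @inheritParams diffcorr
#' @return the fitted `diffcorr` object, invisibly, with the written paths in
#'   attribute `"report_paths"`.
#' @export
run_pipeline <- function(matrix_path, design_path, reference, out_dir,
                         annotation_path = NULL, kgml_dir = NULL,
                         dialect = c("tsv", "series_matrix"),
                         relation_types = c("PPrel", "GErel"),
                         corr_threshold = 0.45, sd_multiplier = 3,
                         retention_floor = 0.8, min_samples = 10,
                         sd_type = c("population", "sample"),
                         aggregate = c("max", "mean"),
                         workers = 1L, chunk_size = 1000L) {
  dialect <- match.arg(dialect)
  if (!is.null(kgml_dir) && !dir.exists(kgml_dir))
    stop("KGML directory not found: ", kgml_dir, call. = FALSE)
  x <- read_expression_matrix(matrix_path, dialect = dialect)
  design <- read_condition_design(design_path)
  annotation <- if (!is.null(annotation_path))
    read_probe_annotation(annotation_path) else NULL
  fit <- diffcorr(x, design, reference,
                  annotation = annotation, pathways = kgml_dir,
                  relation_types = relation_types,
                  corr_threshold = corr_threshold,
                  sd_multiplier = sd_multiplier,
                  retention_floor = retention_floor,
                  min_samples = min_samples, sd_type = sd_type,
                  aggregate = aggregate,
                  workers = workers, chunk_size = chunk_size)

  staging <- tempfile("pathdiffcorr_stage_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  paths <- character(0)
  for (cond in names(fit$pair_results)) {
    p <- file.path(staging, sprintf("pair_correlations_%s.tsv", cond))
    write_pair_correlations(fit$pair_results[[cond]], p)
    paths[paste0("pair_correlations_", cond)] <- p
  }
  paths["differential_pairs"] <- file.path(staging, "differential_pairs.tsv")
  write_differential_pairs(fit$deltas, paths["differential_pairs"])
  paths["pathway_report"] <- file.path(staging, "pathway_report.tsv")
  report <- if (all(c("gene_a", "gene_b", "pathway_ids") %in%
                    names(fit$selected)))
    build_pathway_report(fit$selected, fit$pathways)
  else
    build_pathway_report(NULL)
  write.table(report, paths["pathway_report"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["class_counts"] <- file.path(staging, "class_counts.tsv")
  write_class_counts(fit, paths["class_counts"])
  paths["run_metadata"] <- file.path(staging, "run_metadata.json")
  metadata <- list(
    reference = fit$reference, test = fit$test,
    n_samples = as.list(fit$n_samples),
    config = fit$config,
    inputs = list(matrix = basename(matrix_path),
                  design = basename(design_path),
                  annotation = if (is.null(annotation_path)) NULL else
                    basename(annotation_path),
                  kgml_dir = if (is.null(kgml_dir)) NULL else
                    basename(kgml_dir),
                  dialect = dialect),
    n_pairs = nrow(fit$pairs), n_defined = nrow(fit$deltas),
    n_excluded = fit$n_excluded, n_selected = nrow(fit$selected),
    class_counts = lapply(fit$counts, as.list),
    selection_stats = unclass(fit$stats))
  jsonlite::write_json(metadata, paths["run_metadata"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  final <- file.path(out_dir, basename(paths))
  ok <- file.rename(paths, final)
  if (!all(ok)) {  # cross-device fallback
    file.copy(paths[!ok], final[!ok], overwrite = TRUE)
  }
  names(final) <- names(paths)
  attr(fit, "report_paths") <- final
  invisible(fit)
}
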