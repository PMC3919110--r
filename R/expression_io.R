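# Readers and writers for expression matrices, sample designs and
# probe-to-gene annotations. Matrices are plain numeric matrices with probe
# ids as rownames and sample ids as colnames, on a log2 (RMA-style) scale.

.na_tokens <- c("", "null", "NULL", "NA")

#' Validate an expression matrix
#'
#' Checks the container invariants: a numeric matrix with unique, non-empty
#' probe (row) and sample (column) names, and all non-missing values finite.
#'
#' @param x numeric matrix, probes x samples.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  pid <- rownames(x); sid <- colnames(x)
  if (is.null(pid) || is.null(sid))
    stop("expression matrix must have probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(pid))
    stop("duplicate probe id: ", pid[duplicated(pid)][1L], call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L], call. = FALSE)
  if (any(is.infinite(x)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(x)
}

# Convert a character data.frame (first column = probe ids) to a validated
# numeric matrix; locate any non-numeric cell precisely.
.df_to_matrix <- function(df, source) {
  probe_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(probe_ids))
    stop(sprintf("%s: duplicate probe id: %s", source,
                 probe_ids[duplicated(probe_ids)][1L]), call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop(sprintf("%s: duplicate sample id: %s", source,
                 sample_ids[duplicated(sample_ids)][1L]), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "character"
  vals[vals %in% .na_tokens] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("%s: non-numeric value '%s' at probe %s, sample %s",
                 source, vals[i, j], probe_ids[i], sample_ids[j]),
         call. = FALSE)
  }
  dimnames(num) <- list(probe_ids, sample_ids)
  validate_expression_matrix(num)
  num
}

#' Read an expression matrix
#'
#' Reads a probes x samples matrix of log2-scale intensities. Two dialects are
#' supported: plain TSV (header row of sample ids, first column probe ids) and
#' the GEO series-matrix text format, where only the table block between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` marker lines is
#' parsed and all other `!`-prefixed metadata lines are ignored. Blank,
#' `null` and `NA` cells become missing values.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "series_matrix") {
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines)
    fin <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(fin) != 1L || fin <= beg + 1L)
      stop("series-matrix table markers not found in ", path, call. = FALSE)
    block <- lines[(beg + 1L):(fin - 1L)]
    df <- read.delim(text = block, header = TRUE, sep = "\t",
                     check.names = FALSE, colClasses = "character",
                     quote = "\"")
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character", quote = "")
  }
  if (ncol(df) < 2L)
    stop("expression table needs a probe id column plus >=1 sample column: ",
         path, call. = FALSE)
  .df_to_matrix(df, path)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that write/read
#' round-trips reproduce doubles exactly; missing values are written as the
#' `na` token.
#'
#' @param x numeric matrix with probe rownames and sample colnames.
#' @param path output file path.
#' @param na token used for missing values (default `"null"`, as in GEO
#'   series-matrix files).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, na = "null") {
  validate_expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(row) {
    s <- sprintf("%.17g", row)
    s[is.na(row)] <- na
    paste(s, collapse = "\t")
  })
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample design table
#'
#' Two-column TSV with header `sample_id`, `condition`. Any number of
#' condition labels is accepted at read time; a differential analysis
#' requires exactly two (see [validate_two_conditions()]).
#'
#' @param path file path.
#' @return data.frame with character columns `sample_id` and `condition`.
#' @export
read_condition_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", quote = ""),
    error = function(e) stop("no samples in design file: ", path, call. = FALSE))
  if (nrow(df) == 0L) stop("no samples in design file: ", path, call. = FALSE)
  if (ncol(df) < 2L)
    stop("design file must have columns sample_id, condition: ", path,
         call. = FALSE)
  out <- data.frame(sample_id = df[[1L]], condition = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample id in design: ",
         out$sample_id[duplicated(out$sample_id)][1L], call. = FALSE)
  counts <- table(out$condition)
  message("design: ", paste(sprintf("%s=%d", names(counts), counts),
                            collapse = ", "))
  out
}

#' Require exactly two condition labels
#'
#' @param design data.frame as returned by [read_condition_design()].
#' @return character vector of the two labels, invisibly.
#' @export
validate_two_conditions <- function(design) {
  labs <- unique(design$condition)
  if (length(labs) != 2L)
    stop("differential analysis needs exactly 2 conditions, found ",
         length(labs), ": ", paste(labs, collapse = ", "), call. = FALSE)
  invisible(labs)
}

#' Read a probe-to-gene annotation table
#'
#' Two-column TSV with header `probe_id`, `gene_id`; repeated probe rows
#' accumulate gene ids. Rows with an empty gene field (control probes) are
#' skipped with a warning.
#'
#' @param path file path.
#' @return named list mapping each probe id to a character vector of gene ids.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("annotation file must have columns probe_id, gene_id: ", path,
         call. = FALSE)
  probe <- df[[1L]]; gene <- df[[2L]]
  empty <- is.na(gene) | gene %in% .na_tokens
  if (any(empty)) {
    warning(sum(empty), " annotation row(s) with empty gene id skipped",
            call. = FALSE)
    probe <- probe[!empty]; gene <- gene[!empty]
  }
  lapply(split(gene, factor(probe, levels = unique(probe))), unique)
}

#' Write a probe-to-gene annotation table
#'
#' @param annotation named list, probe id to character vector of gene ids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  probe <- rep(names(annotation), lengths(annotation))
  gene <- unlist(annotation, use.names = FALSE)
  write.table(data.frame(probe_id = probe, gene_id = gene),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
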