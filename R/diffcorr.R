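# Differential correlation selection: per-pair correlation differences
# between two conditions, AVG +/- 3*SD selection thresholds, report builders,
# and the diffcorr() fit function tying the whole analysis together.

#' Per-pair correlation differences between two conditions
#'
#' Joins two per-condition correlation tables on (probe_a, probe_b) and
#' computes `cor_dif = r_ref - r_test` (reference minus test). Pairs with an
#' undefined correlation in either condition are excluded; the number
#' excluded is attached as attribute `"n_excluded"`.
#'
#' @param results_ref,results_test data.frames from [correlate_pairs()] for
#'   the reference and test condition (same pair set).
#' @return data.frame with `probe_a`, `probe_b`, `r_ref`, `r_test`,
#'   `cor_dif`, in the pair order of `results_ref`.
#' @export
delta_correlations <- function(results_ref, results_test) {
  key_ref <- paste(results_ref$probe_a, results_ref$probe_b, sep = "\r")
  key_tst <- paste(results_test$probe_a, results_test$probe_b, sep = "\r")
  if (anyDuplicated(key_ref) || anyDuplicated(key_tst))
    stop("duplicate pairs in correlation results", call. = FALSE)
  idx <- match(key_ref, key_tst)
  if (anyNA(idx))
    stop("pair sets differ between conditions", call. = FALSE)
  out <- data.frame(probe_a = results_ref$probe_a,
                    probe_b = results_ref$probe_b,
                    r_ref = results_ref$r,
                    r_test = results_test$r[idx],
                    stringsAsFactors = FALSE)
  defined <- !is.na(out$r_ref) & !is.na(out$r_test)
  n_excluded <- sum(!defined)
  out <- out[defined, , drop = FALSE]
  rownames(out) <- NULL
  out$cor_dif <- out$r_ref - out$r_test
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Selection thresholds from the correlation differences
#'
#' The mean (`avg`) and standard deviation (`sd`) of all eligible pairs'
#' correlation differences define the selection band
#' `[avg - sd_multiplier*sd, avg + sd_multiplier*sd]`; pairs outside it are
#' called differentially correlated.
#'
#' @param deltas numeric vector of correlation differences (length >= 2).
#' @param sd_multiplier band half-width in SD units (default 3).
#' @param sd_type `"population"` (divide by n, default) or `"sample"` SD.
#' @return object of class `selection_stats`: list with `avg`, `sd`, `lower`,
#'   `upper`, `n_pairs`, `sd_multiplier`.
#' @export
selection_thresholds <- function(deltas, sd_multiplier = 3,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 2L)
    stop("need at least 2 correlation differences to estimate SD",
         call. = FALSE)
  avg <- mean(deltas)
  s <- .sd_of(deltas, sd_type)
  structure(list(avg = avg, sd = s,
                 lower = avg - sd_multiplier * s,
                 upper = avg + sd_multiplier * s,
                 n_pairs = length(deltas), sd_multiplier = sd_multiplier),
            class = "selection_stats")
}

#' @export
print.selection_stats <- function(x, ...) {
  cat(sprintf("selection thresholds over %d pairs: AVG %.4f, SD %.4f\n",
              x$n_pairs, x$avg, x$sd))
  cat(sprintf("  band (AVG +/- %g*SD): [%.4f, %.4f]\n",
              x$sd_multiplier, x$lower, x$upper))
  invisible(x)
}

#' Select differentially correlated pairs
#'
#' A pair is selected when its correlation difference lies strictly outside
#' the selection band (`cor_dif > upper` or `cor_dif < lower`); differences
#' exactly equal to a bound are not selected. The result is sorted by
#' `|cor_dif|` descending, ties broken by pair key.
#'
#' @param pairs data.frame with a `cor_dif` column (from
#'   [delta_correlations()]).
#' @param stats a `selection_stats` object for these pairs' deltas.
#' @return `pairs` with a logical `selected` column, sorted.
#' @export
select_differential <- function(pairs, stats) {
  stopifnot(inherits(stats, "selection_stats"))
  pairs$selected <- pairs$cor_dif > stats$upper | pairs$cor_dif < stats$lower
  key <- if (all(c("probe_a", "probe_b") %in% names(pairs)))
    paste(pairs$probe_a, pairs$probe_b) else as.character(seq_len(nrow(pairs)))
  out <- pairs[order(-abs(pairs$cor_dif), key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count pairs by correlation class
#'
#' @param results data.frame with a `class` column (from
#'   [correlate_pairs()]).
#' @return named integer vector with counts for `coexpressed`, `reverse`,
#'   `unrelated`, `undefined`; the counts always sum to `nrow(results)`.
#' @export
count_by_class <- function(results) {
  lv <- c("coexpressed", "reverse", "unrelated", "undefined")
  out <- table(factor(results$class, levels = lv))
  stats::setNames(as.integer(out), lv)
}

#' Pathway report of selected differential pairs
#'
#' One row per (pathway, selected pair) with the correlation difference
#' formatted with an explicit sign and two decimals (e.g. `+0.37`).
#'
#' @param selected data.frame of selected pairs carrying `gene_a`, `gene_b`,
#'   `cor_dif` and a `;`-collapsed `pathway_ids` column.
#' @param pathways optional named list of `kgml_pathway` objects used to
#'   resolve pathway names (ids are used when absent).
#' @return data.frame with `pathway_id`, `pathway_name`, `pair`
#'   (`"geneA -> geneB"`), `cor_dif` (formatted character), `cor_dif_value`.
#' @export
build_pathway_report <- function(selected, pathways = NULL) {
  empty <- data.frame(pathway_id = character(0), pathway_name = character(0),
                      pair = character(0), cor_dif = character(0),
                      cor_dif_value = numeric(0), stringsAsFactors = FALSE)
  if (is.null(selected) || nrow(selected) == 0L) return(empty)
  if (!all(c("gene_a", "gene_b", "pathway_ids") %in% names(selected)))
    stop("selected pairs must carry gene_a, gene_b and pathway_ids columns",
         call. = FALSE)
  name_of <- function(pid) {
    if (!is.null(pathways) && pid %in% names(pathways))
      pathways[[pid]]$name else pid
  }
  rows <- lapply(seq_len(nrow(selected)), function(i) {
    pids <- strsplit(selected$pathway_ids[i], ";", fixed = TRUE)[[1L]]
    data.frame(pathway_id = pids,
               pathway_name = vapply(pids, name_of, character(1)),
               pair = paste(selected$gene_a[i], "->", selected$gene_b[i]),
               cor_dif = sprintf("%+.2f", selected$cor_dif[i]),
               cor_dif_value = selected$cor_dif[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway_id, -abs(out$cor_dif_value), out$pair), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a two-condition differential correlation analysis
#'
#' The main entry point. For every probe pair, per-condition Pearson
#' correlations are computed after least-squares outlier rejection
#' ([discard_outliers()]), classified against `+/- corr_threshold`, and the
#' between-condition difference `cor_dif = r_ref - r_test` is compared with
#' the `AVG +/- sd_multiplier*SD` band over all eligible pairs
#' ([selection_thresholds()]); pairs strictly outside the band are selected
#' as differentially correlated.
#'
#' Pairs can come from three sources, in order of precedence: an explicit
#' `pairs` table; KGML `pathways` expanded to interacting gene pairs and
#' mapped to probes through `annotation`; or, when both are `NULL`, all
#' probe pairs of the matrix (`probe_a` lexicographically smaller).
#'
#' @param x expression matrix (probes x samples, log2 scale).
#' @param design data.frame with `sample_id`, `condition` (exactly two
#'   labels; every sample must be a column of `x`).
#' @param reference the reference condition label; `cor_dif` is reference
#'   minus test.
#' @param pairs optional data.frame of probe pairs (`probe_a`, `probe_b`,
#'   optionally `gene_a`, `gene_b`, `pathway_ids`, `relation_types`).
#' @param annotation optional probe-to-gene map (needed with `pathways`).
#' @param pathways optional KGML input: a directory, file paths, or a list of
#'   `kgml_pathway` objects.
#' @param relation_types KGML relation types to expand (default PPrel +
#'   GErel).
#' @param corr_threshold classification threshold on r (default 0.45).
#' @param sd_multiplier SD multiplier for both the outlier filter and the
#'   selection band (default 3).
#' @param retention_floor minimum fraction of samples kept by the outlier
#'   filter (default 0.8).
#' @param min_samples minimum complete samples per pair and condition
#'   (default 10).
#' @param sd_type `"population"` (default) or `"sample"` SD throughout.
#' @param aggregate gene-level aggregation when several probe pairs map to
#'   one gene pair: `"max"` (default; representative probe pair with maximum
#'   `|cor_dif|`) or `"mean"` (mean `cor_dif` over probe pairs).
#' @param workers,chunk_size worker-pool configuration ([run_chunked()]).
#' @return an object of class `diffcorr`; see [print.diffcorr()],
#'   [summary.diffcorr()], [coef.diffcorr()], [plot.diffcorr()].
#' @export
diffcorr <- function(x, design, reference,
                     pairs = NULL, annotation = NULL, pathways = NULL,
                     relation_types = c("PPrel", "GErel"),
                     corr_threshold = 0.45, sd_multiplier = 3,
                     retention_floor = 0.8, min_samples = 10,
                     sd_type = c("population", "sample"),
                     aggregate = c("max", "mean"),
                     workers = 1L, chunk_size = 1000L) {
  cl <- match.call()
  sd_type <- match.arg(sd_type)
  aggregate <- match.arg(aggregate)
  stopifnot(retention_floor > 0, retention_floor <= 1,
            corr_threshold > 0, corr_threshold < 1, sd_multiplier > 0)
  validate_expression_matrix(x)
  labs <- validate_two_conditions(design)
  if (!reference %in% labs)
    stop("reference condition '", reference, "' not in design (",
         paste(labs, collapse = ", "), ")", call. = FALSE)
  test <- setdiff(labs, reference)
  absent <- setdiff(design$sample_id, colnames(x))
  if (length(absent) > 0L)
    stop("design sample(s) not in matrix: ",
         paste(head(absent, 5L), collapse = ", "), call. = FALSE)

  pathway_graphs <- NULL
  if (is.null(pairs)) {
    if (!is.null(pathways)) {
      if (is.null(annotation))
        stop("pathway mapping requires a probe annotation", call. = FALSE)
      gene_pairs <- gene_pairs_from_kgml(pathways,
                                         relation_types = relation_types)
      pathway_graphs <- attr(gene_pairs, "pathways")
      pairs <- pairs_to_probes(gene_pairs, annotation)
      if (nrow(pairs) == 0L)
        stop("no probe pairs after pathway mapping", call. = FALSE)
    } else {
      ids <- sort(rownames(x))
      grid <- which(upper.tri(matrix(NA, length(ids), length(ids))),
                    arr.ind = TRUE)
      pairs <- data.frame(probe_a = ids[grid[, "row"]],
                          probe_b = ids[grid[, "col"]],
                          stringsAsFactors = FALSE)
    }
  }
  if (nrow(pairs) == 0L) stop("empty pair set", call. = FALSE)

  args <- list(min_samples = min_samples, corr_threshold = corr_threshold,
               sd_multiplier = sd_multiplier,
               retention_floor = retention_floor, sd_type = sd_type,
               workers = workers, chunk_size = chunk_size)
  samples_of <- function(cond) design$sample_id[design$condition == cond]
  res_ref <- do.call(correlate_pairs,
                     c(list(x = x, pairs = pairs,
                            samples = samples_of(reference),
                            condition = reference), args))
  res_test <- do.call(correlate_pairs,
                      c(list(x = x, pairs = pairs,
                             samples = samples_of(test),
                             condition = test), args))

  deltas <- delta_correlations(res_ref, res_test)
  n_excluded <- attr(deltas, "n_excluded")
  extra <- setdiff(names(pairs), c("probe_a", "probe_b"))
  if (length(extra) > 0L) {
    idx <- match(paste(deltas$probe_a, deltas$probe_b, sep = "\r"),
                 paste(pairs$probe_a, pairs$probe_b, sep = "\r"))
    deltas <- cbind(deltas, pairs[idx, extra, drop = FALSE])
    rownames(deltas) <- NULL
  }
  stats <- selection_thresholds(deltas$cor_dif, sd_multiplier = sd_multiplier,
                                sd_type = sd_type)
  deltas <- select_differential(deltas, stats)
  selected <- deltas[deltas$selected, , drop = FALSE]

  gene_table <- NULL
  if (all(c("gene_a", "gene_b") %in% names(deltas)))
    gene_table <- .aggregate_gene_pairs(deltas, stats, aggregate)

  structure(list(
    call = cl, reference = reference, test = test,
    n_samples = stats::setNames(c(length(samples_of(reference)),
                                  length(samples_of(test))),
                                c(reference, test)),
    pairs = pairs,
    pair_results = stats::setNames(list(res_ref, res_test),
                                   c(reference, test)),
    deltas = deltas, stats = stats, selected = selected,
    gene_table = gene_table,
    counts = stats::setNames(list(count_by_class(res_ref),
                                  count_by_class(res_test)),
                             c(reference, test)),
    n_excluded = n_excluded,
    config = list(corr_threshold = corr_threshold,
                  sd_multiplier = sd_multiplier,
                  retention_floor = retention_floor,
                  min_samples = min_samples, sd_type = sd_type,
                  aggregate = aggregate,
                  relation_types = relation_types,
                  workers = workers, chunk_size = chunk_size),
    pathways = pathway_graphs), class = "diffcorr")
}

# Gene-level view: one row per directed gene pair. "max" keeps the probe
# pair with the largest |cor_dif| as representative (alternates counted);
# "mean" averages cor_dif over the probe pairs and re-applies the band.
.aggregate_gene_pairs <- function(deltas, stats, aggregate) {
  key <- paste(deltas$gene_a, deltas$gene_b, sep = "\r")
  groups <- split(seq_len(nrow(deltas)), key)
  rows <- lapply(groups, function(idx) {
    g <- deltas[idx, , drop = FALSE]
    if (aggregate == "max") {
      rep_i <- idx[which.max(abs(g$cor_dif))]
      out <- deltas[rep_i, , drop = FALSE]
      out$cor_dif_gene <- out$cor_dif
    } else {
      out <- g[1L, , drop = FALSE]
      out$cor_dif_gene <- mean(g$cor_dif)
      out$selected <- out$cor_dif_gene > stats$upper |
                      out$cor_dif_gene < stats$lower
    }
    out$n_probe_pairs <- length(idx)
    out$alternate_probe_pairs <- if (length(idx) > 1L)
      paste(setdiff(paste(g$probe_a, g$probe_b, sep = "|"),
                    paste(out$probe_a, out$probe_b, sep = "|")),
            collapse = ";") else ""
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$cor_dif_gene),
                   paste(out$gene_a, out$gene_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.diffcorr <- function(x, ...) {
  cat("Differential correlation analysis (reference:", x$reference,
      "; test:", x$test, ")\n")
  cat("  samples:", paste(sprintf("%s=%d", names(x$n_samples), x$n_samples),
                          collapse = ", "), "\n")
  cat("  probe pairs:", nrow(x$pairs),
      "| defined in both conditions:", nrow(x$deltas),
      "| excluded:", x$n_excluded, "\n")
  cat(sprintf("  cor_dif band (AVG %+0.4f +/- %g*SD %0.4f): [%.4f, %.4f]\n",
              x$stats$avg, x$stats$sd_multiplier, x$stats$sd,
              x$stats$lower, x$stats$upper))
  cat("  selected differential pairs:", nrow(x$selected), "\n")
  invisible(x)
}

#' Summarise a differential correlation fit
#'
#' Produces the per-condition classification counts (coexpressed `r > 0.45`,
#' reverse `r < -0.45`, unrelated, undefined), the selection statistics and
#' the top selected pairs.
#'
#' @param object a `diffcorr` object.
#' @param n_top number of top pairs to display (default 10).
#' @param ... unused.
#' @return object of class `summary.diffcorr`.
#' @export
summary.diffcorr <- function(object, n_top = 10L, ...) {
  counts <- do.call(rbind, object$counts)
  counts <- cbind(n_samples = object$n_samples[rownames(counts)], counts)
  structure(list(call = object$call, reference = object$reference,
                 test = object$test, class_counts = counts,
                 stats = object$stats, n_pairs = nrow(object$pairs),
                 n_defined = nrow(object$deltas),
                 n_excluded = object$n_excluded,
                 n_selected = nrow(object$selected),
                 top = head(object$selected, n_top)),
            class = "summary.diffcorr")
}

#' @export
print.summary.diffcorr <- function(x, ...) {
  cat("Differential correlation analysis:", x$reference, "vs", x$test, "\n\n")
  cat("Per-condition pair classification:\n")
  print(x$class_counts)
  cat(sprintf("\nPairs: %d total, %d defined in both conditions, %d excluded\n",
              x$n_pairs, x$n_defined, x$n_excluded))
  print(x$stats)
  cat("Selected differential pairs:", x$n_selected, "\n")
  if (nrow(x$top) > 0L) {
    cat("\nTop pairs by |cor_dif|:\n")
    cols <- intersect(c("probe_a", "probe_b", "gene_a", "gene_b",
                        "r_ref", "r_test", "cor_dif", "selected"),
                      names(x$top))
    print(x$top[, cols], digits = 3)
  }
  invisible(x)
}

#' @export
coef.diffcorr <- function(object, ...) {
  stats::setNames(object$deltas$cor_dif,
                  paste(object$deltas$probe_a, object$deltas$probe_b,
                        sep = "|"))
}

#' @export
as.data.frame.diffcorr <- function(x, ...) x$deltas

#' Plot a differential correlation fit
#'
#' Scatter of per-pair correlations, reference condition on the x axis and
#' test condition on the y axis. The dashed diagonals delimit the
#' `AVG +/- k*SD` selection band (`r_test = r_ref - bound`); selected pairs
#' are drawn filled.
#'
#' @param x a `diffcorr` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.diffcorr <- function(x, ...) {
  d <- x$deltas
  graphics::plot(d$r_ref, d$r_test, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = paste0("r (", x$reference, ")"),
                 ylab = paste0("r (", x$test, ")"),
                 col = ifelse(d$selected, "firebrick", "grey50"),
                 pch = ifelse(d$selected, 19, 1), ...)
  graphics::abline(0, 1, col = "grey70")
  graphics::abline(-x$stats$lower, 1, lty = 2, col = "firebrick")
  graphics::abline(-x$stats$upper, 1, lty = 2, col = "firebrick")
  invisible(x)
}
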