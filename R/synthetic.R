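# Synthetic two-condition expression data with planted per-pair correlations,
# planted between-condition correlation differences, gross outlier
# contamination, and a matching probe annotation plus KGML fixture, so the
# full pipeline can be validated without any external download.

#' Describe a synthetic two-condition dataset
#'
#' The defaults emulate a two-condition breast-cancer cohort profiled on a
#' log2-normalised microarray: 160 reference and 89 test samples, baseline
#' log2 intensity N(8, 1), and gross outliers as an additive offset of 8 log2
#' units on one probe of a pair (an aberrant/saturated measurement).
#'
#' @param pair_specs data.frame with columns `gene_a`, `gene_b`, `rho_ref`,
#'   `rho_test`: one planted pair per row (`|rho| < 1`; genes must be unique
#'   across rows so each gene's expression has a single correlation target).
#' @param n_samples named integer vector of length 2, condition label ->
#'   sample count; the first label is the reference condition.
#' @param n_null_probes number of additional independent background probes.
#' @param outlier_rate fraction of samples per planted pair and condition
#'   receiving a gross offset, in `[0, 0.2]` (so the 80% retention floor can
#'   still succeed).
#' @param outlier_magnitude additive offset on the y-axis probe, log2 units.
#' @param baseline_mean,baseline_sd log2-intensity location and scale.
#' @param probes_per_gene probes measuring each planted gene (default 1);
#'   extra probes are noisy copies (measurement noise SD
#'   `0.25 * baseline_sd`), slightly attenuating their pairwise r.
#' @param seed integer seed; identical specs generate identical datasets.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(pair_specs = NULL,
                           n_samples = c(nonrelapse = 160L, relapse = 89L),
                           n_null_probes = 0L, outlier_rate = 0,
                           outlier_magnitude = 8, baseline_mean = 8,
                           baseline_sd = 1, probes_per_gene = 1L,
                           seed = 1L) {
  if (is.null(pair_specs))
    pair_specs <- data.frame(gene_a = character(0), gene_b = character(0),
                             rho_ref = numeric(0), rho_test = numeric(0),
                             stringsAsFactors = FALSE)
  req <- c("gene_a", "gene_b", "rho_ref", "rho_test")
  if (!all(req %in% names(pair_specs)))
    stop("invalid pair_specs: need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (length(n_samples) != 2L || is.null(names(n_samples)) ||
      any(!nzchar(names(n_samples))) || any(n_samples < 1))
    stop("invalid n_samples: need two named positive counts", call. = FALSE)
  if (any(abs(c(pair_specs$rho_ref, pair_specs$rho_test)) >= 1))
    stop("invalid pair_specs: planted |rho| must be < 1", call. = FALSE)
  genes <- c(pair_specs$gene_a, pair_specs$gene_b)
  if (anyDuplicated(genes))
    stop("invalid pair_specs: gene ids must be unique across pairs (gene ",
         genes[duplicated(genes)][1L],
         " cannot satisfy two correlation targets)", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 0.2)
    stop("invalid outlier_rate: must be in [0, 0.2]", call. = FALSE)
  if (outlier_magnitude < 0)
    stop("invalid outlier_magnitude: must be >= 0", call. = FALSE)
  if (baseline_sd <= 0)
    stop("invalid baseline_sd: must be > 0", call. = FALSE)
  if (probes_per_gene < 1L)
    stop("invalid probes_per_gene: must be >= 1", call. = FALSE)
  structure(list(pair_specs = pair_specs,
                 n_samples = stats::setNames(as.integer(n_samples),
                                             names(n_samples)),
                 n_null_probes = as.integer(n_null_probes),
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 probes_per_gene = as.integer(probes_per_gene),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic two-condition spec:",
      paste(sprintf("%s=%d", names(x$n_samples), x$n_samples),
            collapse = ", "),
      "|", nrow(x$pair_specs), "planted pair(s),",
      x$n_null_probes, "null probe(s)\n")
  cat(sprintf("  outliers: rate %.3g, magnitude %.3g log2 units; seed %d\n",
              x$outlier_rate, x$outlier_magnitude, x$seed))
  invisible(x)
}

#' Generate a synthetic two-condition expression dataset
#'
#' Planted pairs are drawn from a bivariate normal with the specified
#' correlation per condition, placed on the log2-intensity scale
#' `baseline_mean +/- baseline_sd`. A fraction `outlier_rate` of samples per
#' planted pair and condition receives an additive `outlier_magnitude` offset
#' on the y-axis probe. Null probes are independent. The global RNG state is
#' saved and restored; the same spec always yields the same dataset.
#'
#' @param spec a [synthetic_spec()] object.
#' @return object of class `synthetic_dataset`: list with `matrix` (probes x
#'   samples), `design`, `annotation` (probe -> gene, planted probes only),
#'   `truth` (data.frame: `gene_a`, `gene_b`, `probe_a`, `probe_b`,
#'   `rho_ref`, `rho_test`, `delta_rho`) and `spec`.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  conds <- names(spec$n_samples)
  sample_ids <- unlist(lapply(conds, function(cc)
    sprintf("%s_%03d", cc, seq_len(spec$n_samples[[cc]]))))
  design <- data.frame(sample_id = sample_ids,
                       condition = rep(conds, spec$n_samples),
                       stringsAsFactors = FALSE)
  n_all <- length(sample_ids)
  cond_idx <- lapply(conds, function(cc) which(design$condition == cc))
  names(cond_idx) <- conds

  np <- nrow(spec$pair_specs)
  k <- spec$probes_per_gene
  probe_rows <- list()
  annotation <- list()
  truth <- NULL
  if (np > 0L) {
    rho_cols <- c(ref = "rho_ref", test = "rho_test")
    for (i in seq_len(np)) {
      ga <- spec$pair_specs$gene_a[i]; gb <- spec$pair_specs$gene_b[i]
      a_sig <- numeric(n_all); b_sig <- numeric(n_all)
      for (ci in seq_along(conds)) {
        idx <- cond_idx[[ci]]
        rho <- spec$pair_specs[[rho_cols[[ci]]]][i]
        z1 <- rnorm(length(idx)); z2 <- rnorm(length(idx))
        a_sig[idx] <- spec$baseline_mean + spec$baseline_sd * z1
        b_sig[idx] <- spec$baseline_mean +
          spec$baseline_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
        n_out <- round(spec$outlier_rate * length(idx))
        if (n_out > 0L) {
          hit <- sample(length(idx), n_out)
          b_sig[idx[hit]] <- b_sig[idx[hit]] + spec$outlier_magnitude
        }
      }
      pa <- sprintf("p_%s_1", ga); pb <- sprintf("p_%s_1", gb)
      probe_rows[[pa]] <- a_sig
      probe_rows[[pb]] <- b_sig
      annotation[[pa]] <- ga; annotation[[pb]] <- gb
      if (k > 1L) {
        for (j in 2:k) {
          noise_sd <- 0.25 * spec$baseline_sd
          pj <- sprintf("p_%s_%d", ga, j)
          probe_rows[[pj]] <- a_sig + rnorm(n_all, sd = noise_sd)
          annotation[[pj]] <- ga
          qj <- sprintf("p_%s_%d", gb, j)
          probe_rows[[qj]] <- b_sig + rnorm(n_all, sd = noise_sd)
          annotation[[qj]] <- gb
        }
      }
      truth <- rbind(truth, data.frame(
        gene_a = ga, gene_b = gb, probe_a = pa, probe_b = pb,
        rho_ref = spec$pair_specs$rho_ref[i],
        rho_test = spec$pair_specs$rho_test[i],
        delta_rho = spec$pair_specs$rho_ref[i] - spec$pair_specs$rho_test[i],
        stringsAsFactors = FALSE))
    }
  }
  if (spec$n_null_probes > 0L) {
    for (j in seq_len(spec$n_null_probes)) {
      probe_rows[[sprintf("null_%05d", j)]] <-
        rnorm(n_all, spec$baseline_mean, spec$baseline_sd)
    }
  }
  if (length(probe_rows) == 0L)
    stop("spec generates no probes: give pair_specs and/or n_null_probes",
         call. = FALSE)
  mat <- do.call(rbind, probe_rows)
  colnames(mat) <- sample_ids
  validate_expression_matrix(mat)
  if (is.null(truth))
    truth <- data.frame(gene_a = character(0), gene_b = character(0),
                        probe_a = character(0), probe_b = character(0),
                        rho_ref = numeric(0), rho_test = numeric(0),
                        delta_rho = numeric(0), stringsAsFactors = FALSE)
  structure(list(matrix = mat, design = design, annotation = annotation,
                 truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dataset:", nrow(x$matrix), "probes x", ncol(x$matrix),
      "samples;", nrow(x$truth), "planted pair(s)\n")
  invisible(x)
}

#' Build a minimal KGML fixture containing given gene pairs
#'
#' Emits a valid KGML document whose relations are exactly the planted gene
#' pairs, so that `parse_kgml()` + `extract_gene_pairs()` recovers them.
#' Genes may be grouped: a pair endpoint naming a group expands, per KGML
#' semantics, to all member genes via a `group` entry with `component`
#' children.
#'
#' @param pair_specs data.frame with columns `gene_a`, `gene_b` (entries may
#'   name a group from `groups`).
#' @param groups optional named list: group name -> character vector of gene
#'   ids.
#' @param pathway_id,pathway_name identifiers written into the document.
#' @param relation_type KGML relation type for all pairs (default `"PPrel"`).
#' @return single string of KGML XML.
#' @export
make_kgml_fixture <- function(pair_specs, groups = NULL,
                              pathway_id = "hsa99999",
                              pathway_name = "synthetic test pathway",
                              relation_type = "PPrel") {
  endpoints <- unique(c(pair_specs$gene_a, pair_specs$gene_b))
  group_names <- names(groups)
  genes <- unique(c(setdiff(endpoints, group_names),
                    unlist(groups, use.names = FALSE)))
  doc <- xml2::xml_new_root("pathway", name = paste0("path:", pathway_id),
                            title = pathway_name, org = "hsa")
  entry_id <- stats::setNames(as.character(seq_along(genes)), genes)
  for (g in genes) {
    xml2::xml_add_child(doc, "entry", id = entry_id[[g]], name = g,
                        type = "gene")
  }
  next_id <- length(genes)
  for (gn in group_names) {
    next_id <- next_id + 1L
    e <- xml2::xml_add_child(doc, "entry", id = as.character(next_id),
                             name = "undefined", type = "group")
    for (m in groups[[gn]])
      xml2::xml_add_child(e, "component", id = entry_id[[m]])
    entry_id[[gn]] <- as.character(next_id)
  }
  for (i in seq_len(nrow(pair_specs))) {
    xml2::xml_add_child(doc, "relation",
                        entry1 = entry_id[[pair_specs$gene_a[i]]],
                        entry2 = entry_id[[pair_specs$gene_b[i]]],
                        type = relation_type)
  }
  as.character(doc)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the TSV formats the readers consume (`matrix.tsv`, `design.tsv`,
#' `annotation.tsv`, `truth.tsv`) plus a KGML fixture (`pathway.xml`)
#' containing the planted gene pairs.
#'
#' @param dataset a `synthetic_dataset` object.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             design = file.path(dir, "design.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"),
             kgml = file.path(dir, "pathway.xml"))
  write_expression_matrix(dataset$matrix, paths[["matrix"]])
  write.table(dataset$design, paths[["design"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_probe_annotation(dataset$annotation, paths[["annotation"]])
  write.table(dataset$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(make_kgml_fixture(dataset$truth), paths[["kgml"]])
  invisible(paths)
}
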