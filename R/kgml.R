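# KGML (KEGG Markup Language) parsing: pathway XML -> directed interacting
# gene pairs -> probe pairs. Works entirely from local KGML files; no KEGG
# API access is performed.

.kgml_relation_types <- c("PPrel", "GErel", "ECrel", "PCrel", "maplink")

#' Parse a KGML pathway file
#'
#' Reads a KEGG pathway XML document into a light graph structure: `entry`
#' elements of type `"gene"` keep all gene ids listed in their `name`
#' attribute; entries of type `"group"` are expanded to the union of their
#' components' gene ids; `relation` elements are kept with their `type`
#' attribute. Relations referencing an unknown entry id are skipped with a
#' warning.
#'
#' @param x path to a KGML file, or a single string of KGML XML content.
#' @return an object of class `kgml_pathway`: a list with `pathway_id`,
#'   `name`, `entries` (named list; each element has `id`, `type` and a
#'   character vector `genes`) and `relations` (data.frame with `entry1`,
#'   `entry2`, `type`).
#' @export
parse_kgml <- function(x) {
  doc <- xml2::read_xml(x)
  if (xml2::xml_name(doc) != "pathway")
    stop("not a KGML document: root element is <", xml2::xml_name(doc), ">",
         call. = FALSE)
  pid <- sub("^path:", "", xml2::xml_attr(doc, "name"))
  title <- xml2::xml_attr(doc, "title")
  if (is.na(title)) title <- pid

  nodes <- xml2::xml_find_all(doc, "./entry")
  entries <- list()
  components <- list()
  for (e in nodes) {
    id <- xml2::xml_attr(e, "id")
    type <- xml2::xml_attr(e, "type")
    genes <- character(0)
    if (identical(type, "gene")) {
      nm <- xml2::xml_attr(e, "name")
      if (!is.na(nm) && nzchar(nm))
        genes <- setdiff(strsplit(nm, "[[:space:]]+")[[1L]], c("", "undefined"))
      if (length(genes) == 0L)
        warning("gene entry ", id, " in ", pid, " lists no gene ids",
                call. = FALSE)
    }
    if (identical(type, "group"))
      components[[id]] <- xml2::xml_attr(xml2::xml_find_all(e, "./component"),
                                         "id")
    entries[[id]] <- list(id = id, type = type, genes = genes)
  }
  # group entries expand to the union of their components' genes
  for (id in names(components)) {
    comp <- components[[id]]
    known <- comp[comp %in% names(entries)]
    entries[[id]]$genes <-
      unique(unlist(lapply(entries[known], `[[`, "genes"), use.names = FALSE))
  }

  rel_nodes <- xml2::xml_find_all(doc, "./relation")
  relations <- data.frame(entry1 = xml2::xml_attr(rel_nodes, "entry1"),
                          entry2 = xml2::xml_attr(rel_nodes, "entry2"),
                          type = xml2::xml_attr(rel_nodes, "type"),
                          stringsAsFactors = FALSE)
  unknown <- !(relations$entry1 %in% names(entries)) |
             !(relations$entry2 %in% names(entries))
  if (any(unknown)) {
    warning(sum(unknown), " relation(s) in ", pid,
            " reference unknown entries and were skipped", call. = FALSE)
    relations <- relations[!unknown, , drop = FALSE]
  }
  structure(list(pathway_id = pid, name = title, entries = entries,
                 relations = relations),
            class = "kgml_pathway")
}

#' @export
print.kgml_pathway <- function(x, ...) {
  n_gene <- sum(vapply(x$entries, function(e) identical(e$type, "gene"),
                       logical(1)))
  cat("KGML pathway", x$pathway_id, "-", x$name, "\n")
  cat("  entries:", length(x$entries), "(", n_gene, "gene )",
      " relations:", nrow(x$relations), "\n")
  invisible(x)
}

#' Extract directed gene pairs from a parsed pathway
#'
#' Every relation of a requested type is expanded to the cartesian product of
#' the gene sets of its two endpoint entries (groups contribute the union of
#' their components). Direction follows the KGML relation (entry1 to entry2).
#' Self-pairs are removed and duplicate pairs are merged with the union of
#' their relation types. The result is sorted by (gene_a, gene_b) and is
#' therefore independent of entry order in the XML.
#'
#' @param graph a `kgml_pathway` object.
#' @param relation_types subset of `c("PPrel","GErel","ECrel","PCrel",
#'   "maplink")`; default keeps protein-protein and gene-expression relations.
#' @return data.frame with columns `gene_a`, `gene_b`, `pathway_ids`,
#'   `relation_types` (the two last `;`-collapsed).
#' @export
extract_gene_pairs <- function(graph, relation_types = c("PPrel", "GErel")) {
  stopifnot(inherits(graph, "kgml_pathway"))
  bad <- setdiff(relation_types, .kgml_relation_types)
  if (length(bad) > 0L)
    stop("unknown relation type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rel <- graph$relations
  rel <- rel[rel$type %in% relation_types, , drop = FALSE]
  if (nrow(rel) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pathway_ids = character(0),
                      relation_types = character(0),
                      stringsAsFactors = FALSE))
  ga <- character(0); gb <- character(0); rt <- character(0)
  for (i in seq_len(nrow(rel))) {
    a <- graph$entries[[rel$entry1[i]]]$genes
    b <- graph$entries[[rel$entry2[i]]]$genes
    if (length(a) == 0L || length(b) == 0L) next
    grid <- expand.grid(gene_a = a, gene_b = b, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    ga <- c(ga, grid$gene_a); gb <- c(gb, grid$gene_b)
    rt <- c(rt, rep(rel$type[i], nrow(grid)))
  }
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]; rt <- rt[keep]
  if (length(ga) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pathway_ids = character(0),
                      relation_types = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(ga, gb, sep = "\r")
  types <- vapply(split(rt, key), function(v)
    paste(sort(unique(v)), collapse = ";"), character(1))
  uk <- names(types)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, character(1), 1L),
                    gene_b = vapply(parts, `[`, character(1), 2L),
                    pathway_ids = graph$pathway_id,
                    relation_types = unname(types),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Merge gene-pair tables from several pathways
#'
#' Duplicate directed pairs across pathways are merged with the union of
#' their pathway ids and relation types.
#'
#' @param pair_tables list of data.frames as returned by
#'   [extract_gene_pairs()].
#' @return a single merged, sorted data.frame of the same shape.
#' @export
merge_gene_pairs <- function(pair_tables) {
  all <- do.call(rbind, pair_tables)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pathway_ids = character(0),
                      relation_types = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(all$gene_a, all$gene_b, sep = "\r")
  merge_col <- function(col) vapply(split(col, key), function(v)
    paste(sort(unique(unlist(strsplit(v, ";", fixed = TRUE)))),
          collapse = ";"), character(1))
  pw <- merge_col(all$pathway_ids)
  rt <- merge_col(all$relation_types)
  parts <- strsplit(names(pw), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, character(1), 1L),
                    gene_b = vapply(parts, `[`, character(1), 2L),
                    pathway_ids = unname(pw),
                    relation_types = unname(rt),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Gene pairs from a directory (or list) of KGML files
#'
#' @param x directory containing `.xml` KGML files, a character vector of
#'   file paths, or a list of `kgml_pathway` objects.
#' @param relation_types passed to [extract_gene_pairs()].
#' @return merged gene-pair data.frame; the parsed pathways are attached as
#'   attribute `"pathways"` (named by pathway id).
#' @export
gene_pairs_from_kgml <- function(x, relation_types = c("PPrel", "GErel")) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    x <- list.files(x, pattern = "\\.xml$", full.names = TRUE)
    if (length(x) == 0L)
      stop("no .xml KGML files found", call. = FALSE)
  }
  graphs <- if (is.list(x) && all(vapply(x, inherits, logical(1),
                                         "kgml_pathway"))) x
            else lapply(x, parse_kgml)
  names(graphs) <- vapply(graphs, `[[`, character(1), "pathway_id")
  pairs <- merge_gene_pairs(lapply(graphs, extract_gene_pairs,
                                   relation_types = relation_types))
  attr(pairs, "pathways") <- graphs
  pairs
}

#' Map gene pairs to probe pairs
#'
#' Every probe measuring `gene_a` is crossed with every probe measuring
#' `gene_b` (a gene may have several probes and vice versa). Pairs in which
#' either gene has no probe in the annotation are dropped with one summary
#' warning; probe self-pairs are removed.
#'
#' @param pairs gene-pair data.frame (columns `gene_a`, `gene_b`, and
#'   optionally `pathway_ids`, `relation_types`).
#' @param annotation named list probe id -> gene ids, as returned by
#'   [read_probe_annotation()].
#' @return data.frame with columns `probe_a`, `probe_b`, `gene_a`, `gene_b`
#'   plus any pathway columns present in `pairs`.
#' @export
pairs_to_probes <- function(pairs, annotation) {
  gene <- unlist(annotation, use.names = FALSE)
  probe <- rep(names(annotation), lengths(annotation))
  gene2probe <- split(probe, gene)
  rows <- vector("list", nrow(pairs))
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    pa <- gene2probe[[pairs$gene_a[i]]]
    pb <- gene2probe[[pairs$gene_b[i]]]
    if (is.null(pa) || is.null(pb)) { dropped <- dropped + 1L; next }
    grid <- expand.grid(probe_a = pa, probe_b = pb, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$probe_a != grid$probe_b, , drop = FALSE]
    if (nrow(grid) == 0L) next
    rows[[i]] <- cbind(grid, pairs[rep(i, nrow(grid)), , drop = FALSE],
                       row.names = NULL)
  }
  if (dropped > 0L)
    warning(dropped, " gene pair(s) dropped: gene without probe annotation",
            call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(data.frame(probe_a = character(0), probe_b = character(0),
                            stringsAsFactors = FALSE),
                 pairs[integer(0), , drop = FALSE])
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$probe_a, out$probe_b), , drop = FALSE]
}

#' Write gene pairs as an edge-list TSV
#'
#' Columns: `pathway_id`, `gene_a`, `gene_b`, `relation_type`.
#'
#' @param pairs gene-pair data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_pairs <- function(pairs, path) {
  write.table(data.frame(pathway_id = pairs$pathway_ids,
                         gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                         relation_type = pairs$relation_types),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
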