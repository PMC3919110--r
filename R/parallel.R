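# Chunked map-only execution on a local worker pool (the semantics of a
# map-reduce job with zero reducers): partition the items into contiguous
# chunks, run a pure per-item task on each chunk independently, optionally
# write each chunk's output to its own file, and concatenate chunk results in
# chunk order. Output is invariant to the number of workers and to the chunk
# size.

#' Partition items into contiguous chunks
#'
#' @param n_items total number of items (>= 0).
#' @param chunk_size positive chunk size.
#' @return object of class `chunk_plan`: list with `n_items`, `chunk_size`
#'   and `chunks`, a data.frame of 1-based inclusive ranges (`from`, `to`)
#'   that are disjoint, ordered and cover `1:n_items` exactly.
#' @export
chunk_plan <- function(n_items, chunk_size) {
  if (length(chunk_size) != 1L || is.na(chunk_size) || chunk_size < 1)
    stop("chunk_size must be >= 1", call. = FALSE)
  if (n_items < 0) stop("n_items must be >= 0", call. = FALSE)
  n_items <- as.integer(n_items); chunk_size <- as.integer(chunk_size)
  if (n_items == 0L) {
    chunks <- data.frame(from = integer(0), to = integer(0))
  } else {
    from <- seq.int(1L, n_items, by = chunk_size)
    chunks <- data.frame(from = from, to = pmin(from + chunk_size - 1L,
                                                n_items))
  }
  structure(list(n_items = n_items, chunk_size = chunk_size, chunks = chunks),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat("chunk plan:", x$n_items, "items in", nrow(x$chunks),
      "chunk(s) of size", x$chunk_size, "\n")
  invisible(x)
}

#' Run a pure per-item task over chunks on a worker pool
#'
#' Applies `fun` to every element of `items`, chunk by chunk. Chunks run in
#' parallel via forked workers when `workers > 1`; results are always
#' combined in input order, so the output is identical to
#' `lapply(items, fun)` regardless of `workers` and `chunk_size` (the task
#' must be deterministic and side-effect free). A failure in any chunk
#' aborts the run with an error naming the chunk and the failing item.
#'
#' When `intermediate_dir` is given, each chunk serialises its results to its
#' own file (`chunk_000001.tsv` for one-row data.frame results, otherwise
#' `chunk_000001.rds`) before the combine step, mirroring map tasks that
#' write their output directly to the file system.
#'
#' @param items vector or list of items; names, if present, are used in error
#'   messages.
#' @param fun function of one item.
#' @param chunk_size items per chunk (default 1000).
#' @param workers number of parallel workers (default 1 = sequential).
#' @param plan optional precomputed [chunk_plan()] (must match
#'   `length(items)`).
#' @param intermediate_dir optional directory for per-chunk output files.
#' @return list of results, one per item, in input order.
#' @export
run_chunked <- function(items, fun, chunk_size = 1000L, workers = 1L,
                        plan = NULL, intermediate_dir = NULL) {
  if (is.null(plan)) plan <- chunk_plan(length(items), chunk_size)
  stopifnot(inherits(plan, "chunk_plan"))
  if (plan$n_items != length(items))
    stop("chunk plan covers ", plan$n_items, " items but ", length(items),
         " were given", call. = FALSE)
  if (length(items) == 0L) return(list())
  if (!is.null(intermediate_dir))
    dir.create(intermediate_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- names(items)
  if (is.null(labels)) labels <- as.character(seq_along(items))

  run_one <- function(ci) {
    rng <- plan$chunks[ci, ]
    idx <- seq.int(rng$from, rng$to)
    res <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      res[[j]] <- tryCatch(fun(items[[i]]), error = function(e)
        stop(sprintf("chunk %d: task failed on item %s: %s",
                     ci, labels[i], conditionMessage(e)), call. = FALSE))
    }
    if (!is.null(intermediate_dir)) {
      if (all(vapply(res, is.data.frame, logical(1)))) {
        write.table(do.call(rbind, res),
                    file.path(intermediate_dir,
                              sprintf("chunk_%06d.tsv", ci)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        saveRDS(res, file.path(intermediate_dir,
                               sprintf("chunk_%06d.rds", ci)))
      }
    }
    res
  }

  n_chunks <- nrow(plan$chunks)
  workers <- max(1L, as.integer(workers))
  if (workers > 1L && .Platform$OS.type == "unix" && n_chunks > 1L) {
    chunk_res <- parallel::mclapply(seq_len(n_chunks), run_one,
                                    mc.cores = workers, mc.preschedule = TRUE)
    failed <- vapply(chunk_res, inherits, logical(1), "try-error")
    if (any(failed))
      stop(conditionMessage(attr(chunk_res[[which(failed)[1L]]], "condition")),
           call. = FALSE)
  } else {
    chunk_res <- lapply(seq_len(n_chunks), run_one)
  }
  do.call(c, chunk_res)
}
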