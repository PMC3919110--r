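# Per-pair correlation with least-squares outlier rejection.
#
# For one probe pair in one condition: ordinary least squares of the second
# probe (y) on the first (x), discard samples whose squared residual exceeds
# mean + sd_multiplier * SD of the squared residuals (never discarding more
# than a 1 - retention_floor fraction), then Pearson correlation on the kept
# samples and a three-way classification against +/- corr_threshold.

#' Ordinary least-squares line fit
#'
#' Closed-form simple regression of `y` on `x` via the normal equations,
#' returning per-sample squared residuals. A constant `x` makes the slope
#' undefined: the fit is flagged degenerate and residuals are `NA`, which
#' downstream code treats as "skip outlier filtering".
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return list with `slope`, `intercept`, `squared_residuals`, `degenerate`.
#' @export
fit_line <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("line fit needs at least 3 points", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                squared_residuals = rep(NA_real_, n), degenerate = TRUE))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  list(slope = slope, intercept = intercept,
       squared_residuals = (y - (intercept + slope * x))^2,
       degenerate = FALSE)
}

.sd_of <- function(v, sd_type) {
  m <- mean(v)
  if (sd_type == "population") sqrt(mean((v - m)^2)) else stats::sd(v)
}

#' Discard outlier samples by squared regression residual
#'
#' Single-pass filter: fit a least-squares line, compute each sample's squared
#' residual, and flag samples whose squared residual strictly exceeds
#' `mean + sd_multiplier * SD` of the squared residuals. At most
#' `floor((1 - retention_floor) * n)` samples are discarded — at least an
#' 80% fraction of samples is always retained at the defaults — dropping the
#' largest residuals first (ties broken by sample order). There is no
#' iterative refit.
#'
#' @param x,y numeric vectors, no missing values.
#' @param sd_multiplier multiplier on the SD of squared residuals (default 3).
#' @param retention_floor minimum fraction of samples retained (default 0.8).
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n-1) SD of the squared residuals.
#' @return object of class `outlier_filter`: list with `slope`, `intercept`,
#'   `squared_residuals`, `keep_mask`, `threshold`, `n_total`, `n_used`.
#' @export
discard_outliers <- function(x, y, sd_multiplier = 3, retention_floor = 0.8,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  fit <- fit_line(x, y)
  n <- length(x)
  keep <- rep(TRUE, n)
  threshold <- NA_real_
  if (!fit$degenerate) {
    sq <- fit$squared_residuals
    threshold <- mean(sq) + sd_multiplier * .sd_of(sq, sd_type)
    flagged <- which(sq > threshold)
    # small epsilon so e.g. (1 - 0.8) * 20 = 3.999... still caps at 4
    cap <- floor((1 - retention_floor) * n + 1e-9)
    if (length(flagged) > cap)
      flagged <- flagged[order(-sq[flagged], flagged)][seq_len(cap)]
    keep[flagged] <- FALSE
  }
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 squared_residuals = fit$squared_residuals,
                 keep_mask = keep, threshold = threshold,
                 n_total = n, n_used = sum(keep)),
            class = "outlier_filter")
}

#' @export
print.outlier_filter <- function(x, ...) {
  cat("outlier filter: kept", x$n_used, "of", x$n_total, "samples",
      sprintf("(threshold %.4g)\n", x$threshold))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin guard around the product-moment correlation: returns `NA` (an
#' undefined correlation) when fewer than 3 paired values are available or
#' when either vector is constant.
#'
#' @param x,y numeric vectors of equal length, no missing values.
#' @return correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) return(NA_real_)
  if (sum((x - mean(x))^2) == 0 || sum((y - mean(y))^2) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

#' Classify a correlation against the coexpression threshold
#'
#' Strict inequalities: `r > threshold` is `"coexpressed"`, `r < -threshold`
#' is `"reverse"`, anything in the closed interval `[-threshold, threshold]`
#' is `"unrelated"`, and `NA` is `"undefined"`. Vectorised over `r`.
#'
#' @param r numeric vector of correlations (may contain `NA`).
#' @param threshold positive classification threshold (default 0.45).
#' @return character vector over
#'   `c("coexpressed", "reverse", "unrelated", "undefined")`.
#' @export
classify_cor <- function(r, threshold = 0.45) {
  stopifnot(threshold > 0, threshold < 1)
  out <- rep("undefined", length(r))
  out[!is.na(r) & r > threshold] <- "coexpressed"
  out[!is.na(r) & r < -threshold] <- "reverse"
  out[!is.na(r) & r >= -threshold & r <= threshold] <- "unrelated"
  out
}

#' Correlate one probe pair in one sample subset
#'
#' Restricts to samples where both probes are non-missing (`n_total`),
#' applies the outlier filter with x = `probe_a` values and y = `probe_b`
#' values, computes Pearson correlation on the kept samples and classifies
#' it. Pairs with fewer than `min_samples` complete samples are reported as
#' class `"undefined"` rather than estimated unstably.
#'
#' @param x expression matrix (probes x samples).
#' @param probe_a,probe_b probe ids (x-axis and y-axis probe, respectively).
#' @param samples sample ids to use (default: all columns).
#' @param condition optional condition label copied into the result.
#' @param min_samples minimum complete samples required (default 10).
#' @param corr_threshold classification threshold (default 0.45).
#' @param sd_multiplier,retention_floor,sd_type passed to
#'   [discard_outliers()].
#' @return one-row data.frame: `probe_a`, `probe_b`, `condition`, `n_total`,
#'   `n_used`, `r`, `class`.
#' @export
correlate_pair <- function(x, probe_a, probe_b, samples = NULL,
                           condition = NA_character_, min_samples = 10,
                           corr_threshold = 0.45, sd_multiplier = 3,
                           retention_floor = 0.8,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!probe_a %in% rownames(x)) stop("unknown probe: ", probe_a, call. = FALSE)
  if (!probe_b %in% rownames(x)) stop("unknown probe: ", probe_b, call. = FALSE)
  if (is.null(samples)) samples <- colnames(x)
  va <- x[probe_a, samples]
  vb <- x[probe_b, samples]
  ok <- !is.na(va) & !is.na(vb)
  n_total <- sum(ok)
  row <- data.frame(probe_a = probe_a, probe_b = probe_b,
                    condition = condition, n_total = n_total,
                    n_used = n_total, r = NA_real_, class = "undefined",
                    stringsAsFactors = FALSE)
  if (n_total < max(min_samples, 3L)) return(row)
  va <- va[ok]; vb <- vb[ok]
  filt <- discard_outliers(va, vb, sd_multiplier = sd_multiplier,
                           retention_floor = retention_floor,
                           sd_type = sd_type)
  r <- pearson_cor(va[filt$keep_mask], vb[filt$keep_mask])
  row$n_used <- filt$n_used
  row$r <- r
  row$class <- classify_cor(r, corr_threshold)
  row
}

#' Correlate many probe pairs in one condition
#'
#' Runs [correlate_pair()] over a pair table through the chunked worker-pool
#' engine ([run_chunked()]); results are returned in input order regardless
#' of `workers` and `chunk_size`.
#'
#' @param x expression matrix.
#' @param pairs data.frame with columns `probe_a`, `probe_b`.
#' @param samples sample ids to use (e.g. one condition's samples).
#' @param condition condition label recorded in the results.
#' @param workers,chunk_size,intermediate_dir passed to [run_chunked()].
#' @inheritParams correlate_pair
#' @return data.frame, one row per input pair (same order), with the
#'   [correlate_pair()] columns.
#' @export
correlate_pairs <- function(x, pairs, samples = NULL,
                            condition = NA_character_, min_samples = 10,
                            corr_threshold = 0.45, sd_multiplier = 3,
                            retention_floor = 0.8,
                            sd_type = c("population", "sample"),
                            workers = 1L, chunk_size = 1000L,
                            intermediate_dir = NULL) {
  sd_type <- match.arg(sd_type)
  if (is.null(samples)) samples <- colnames(x)
  missing_p <- setdiff(unique(c(pairs$probe_a, pairs$probe_b)), rownames(x))
  if (length(missing_p) > 0L)
    stop("probe(s) not in matrix: ",
         paste(head(missing_p, 5L), collapse = ", "), call. = FALSE)
  xs <- x[, samples, drop = FALSE]
  ia <- match(pairs$probe_a, rownames(xs))
  ib <- match(pairs$probe_b, rownames(xs))
  items <- seq_len(nrow(pairs))
  names(items) <- paste(pairs$probe_a, pairs$probe_b, sep = "|")
  task <- function(i) {
    va <- xs[ia[i], ]; vb <- xs[ib[i], ]
    ok <- !is.na(va) & !is.na(vb)
    n_total <- sum(ok)
    if (n_total < max(min_samples, 3L))
      return(list(n_total = n_total, n_used = n_total, r = NA_real_))
    va <- va[ok]; vb <- vb[ok]
    filt <- discard_outliers(va, vb, sd_multiplier = sd_multiplier,
                             retention_floor = retention_floor,
                             sd_type = sd_type)
    list(n_total = n_total, n_used = filt$n_used,
         r = pearson_cor(va[filt$keep_mask], vb[filt$keep_mask]))
  }
  res <- run_chunked(items, task, chunk_size = chunk_size, workers = workers,
                     intermediate_dir = intermediate_dir)
  r <- vapply(res, `[[`, numeric(1), "r")
  data.frame(probe_a = pairs$probe_a, probe_b = pairs$probe_b,
             condition = condition,
             n_total = vapply(res, `[[`, numeric(1), "n_total"),
             n_used = vapply(res, `[[`, numeric(1), "n_used"),
             r = r, class = classify_cor(r, corr_threshold),
             stringsAsFactors = FALSE)
}

#' Average log2 fold change of one probe between conditions
#'
#' Mean expression in the test condition minus mean expression in the
#' reference condition (values are assumed log2 scale, so the difference of
#' means is an average log2 fold change). Missing values are excluded from
#' the means.
#'
#' @param x expression matrix.
#' @param probe probe id.
#' @param design two-condition design data.frame.
#' @param reference reference condition label (the other label is the test).
#' @return numeric log2 fold change; `NA` with a warning when a condition has
#'   no non-missing values.
#' @export
log2_fold_change <- function(x, probe, design, reference) {
  labs <- validate_two_conditions(design)
  if (!reference %in% labs)
    stop("reference condition '", reference, "' not in design", call. = FALSE)
  test <- setdiff(labs, reference)
  v_ref <- x[probe, design$sample_id[design$condition == reference]]
  v_tst <- x[probe, design$sample_id[design$condition == test]]
  if (all(is.na(v_ref)) || all(is.na(v_tst))) {
    warning("log2 fold change undefined for probe ", probe,
            ": a condition has no non-missing values", call. = FALSE)
    return(NA_real_)
  }
  mean(v_tst, na.rm = TRUE) - mean(v_ref, na.rm = TRUE)
}
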