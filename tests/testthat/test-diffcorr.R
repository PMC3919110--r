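make_results <- function(r, condition = "c", pa = NULL, pb = NULL) {
  n <- length(r)
  if (is.null(pa)) pa <- sprintf("pa%03d", seq_len(n))
  if (is.null(pb)) pb <- sprintf("pb%03d", seq_len(n))
  data.frame(probe_a = pa, probe_b = pb,
             condition = rep_len(condition, n),
             n_total = rep_len(100L, n), n_used = rep_len(100L, n), r = r,
             class = classify_cor(r), stringsAsFactors = FALSE)
}

test_that("delta_correlations subtracts test from reference per pair", {
  ref <- make_results(c(0.3, 0.9, NA, 0.1, -0.4))
  tst <- make_results(c(0.3, -0.9, 0.2, NA, 0.25))
  d <- delta_correlations(ref, tst)
  expect_identical(nrow(d), 3L)
  expect_identical(attr(d, "n_excluded"), 2L)
  expect_equal(d$cor_dif, c(0, 1.8, -0.65))
  expect_equal(d$cor_dif, d$r_ref - d$r_test)
  # join is by pair key, not position
  tst_shuffled <- tst[c(3, 1, 5, 2, 4), ]
  expect_equal(delta_correlations(ref, tst_shuffled), d,
               ignore_attr = TRUE)
  expect_error(delta_correlations(ref, make_results(0.1, "t", "x", "y")),
               "pair sets differ")
})

test_that("selection_thresholds computes AVG +/- k*SD", {
  s <- selection_thresholds(rep(0.3, 5))
  expect_equal(s$avg, 0.3)
  expect_equal(s$sd, 0)
  expect_equal(c(s$lower, s$upper), c(0.3, 0.3))

  s2 <- selection_thresholds(c(-1, 1))
  expect_equal(s2$avg, 0)
  expect_equal(s2$lower, -s2$upper)

  # direct-formula oracle, both SD conventions
  set.seed(8)
  d <- runif(100, -2, 2)
  s3 <- selection_thresholds(d)
  m <- sum(d) / 100
  sd_pop <- sqrt(sum((d - m)^2) / 100)
  expect_equal(s3$avg, m, tolerance = 1e-12)
  expect_equal(s3$sd, sd_pop, tolerance = 1e-12)
  expect_equal(s3$upper, m + 3 * sd_pop, tolerance = 1e-12)
  s4 <- selection_thresholds(d, sd_type = "sample")
  expect_equal(s4$sd, sqrt(sum((d - m)^2) / 99), tolerance = 1e-12)
  # configurable multiplier
  s5 <- selection_thresholds(d, sd_multiplier = 2)
  expect_equal(s5$upper, m + 2 * sd_pop, tolerance = 1e-12)

  expect_error(selection_thresholds(0.5), "at least 2")
})

test_that("select_differential uses strict inequalities and sorts output", {
  # all deltas identical: sd = 0, strict inequality selects nothing
  d0 <- data.frame(probe_a = letters[1:4], probe_b = LETTERS[1:4],
                   cor_dif = rep(0.2, 4))
  s0 <- selection_thresholds(d0$cor_dif)
  expect_false(any(select_differential(d0, s0)$selected))

  # 997 near-null deltas plus planted +/-0.9: exactly the planted selected
  set.seed(15)
  deltas <- c(rnorm(997, 0, 0.01), 0.9, -0.9)
  dd <- data.frame(probe_a = sprintf("a%04d", seq_along(deltas)),
                   probe_b = sprintf("b%04d", seq_along(deltas)),
                   cor_dif = deltas)
  st <- selection_thresholds(deltas)
  # brute-force oracle on the same vector
  expect_identical(sum(deltas > st$upper | deltas < st$lower), 2L)
  sel <- select_differential(dd, st)
  expect_identical(sum(sel$selected), 2L)
  expect_setequal(sel$cor_dif[sel$selected], c(0.9, -0.9))
  # sorted by |cor_dif| descending
  expect_identical(sel$cor_dif[1:2][order(-sel$cor_dif[1:2])], c(0.9, -0.9))
  expect_true(!is.unsorted(rev(abs(sel$cor_dif))))

  # a delta exactly on a bound is not selected
  st2 <- selection_thresholds(c(-0.5, 0.5))  # avg 0, pop sd 0.5, upper 1.5
  expect_equal(st2$upper, 1.5)
  db <- data.frame(cor_dif = c(1.5, -1.5, 1.5 + 1e-12))
  selb <- select_differential(db, st2)
  expect_identical(selb$selected, c(TRUE, FALSE, FALSE))

  # idempotent and order-independent
  sel2 <- select_differential(sel, st)
  expect_identical(sel2$selected, sel$selected)
  perm <- dd[sample(nrow(dd)), ]
  sel3 <- select_differential(perm, st)
  expect_identical(sel3$cor_dif, sel$cor_dif)
})

test_that("count_by_class partitions results exhaustively", {
  res <- make_results(c(0.5, -0.5, 0))
  expect_identical(count_by_class(res),
                   c(coexpressed = 1L, reverse = 1L, unrelated = 1L,
                     undefined = 0L))
  expect_identical(sum(count_by_class(res)), nrow(res))
  empty <- make_results(numeric(0))
  expect_identical(sum(count_by_class(empty)), 0L)
  set.seed(3)
  res50 <- make_results(runif(50, -1, 1))
  cc <- count_by_class(res50)
  expect_identical(sum(cc), 50L)
  expect_identical(unname(cc["coexpressed"]), sum(res50$r > 0.45))
  expect_identical(unname(cc["reverse"]), sum(res50$r < -0.45))
})

test_that("build_pathway_report emits one row per pathway and pair", {
  sel <- data.frame(gene_a = c("NFKB2", "JUN"), gene_b = c("PTGS2", "MMP1"),
                    cor_dif = c(0.37, -0.29),
                    pathway_ids = c("hsa05200;hsa04064", "hsa05200"),
                    stringsAsFactors = FALSE)
  rep1 <- build_pathway_report(sel)
  expect_identical(nrow(rep1), 3L)
  expect_identical(rep1$cor_dif[rep1$pair == "NFKB2 -> PTGS2"],
                   c("+0.37", "+0.37"))
  expect_identical(rep1$cor_dif[rep1$pair == "JUN -> MMP1"], "-0.29")

  # pathway names resolved from parsed KGML when available
  graphs <- list(hsa05200 = parse_kgml(sub("hsa00001", "hsa05200",
                                           sub("tiny pathway",
                                               "Pathways in cancer",
                                               tiny_kgml()))))
  rep2 <- build_pathway_report(sel, graphs)
  expect_identical(unique(rep2$pathway_name[rep2$pathway_id == "hsa05200"]),
                   "Pathways in cancer")

  # empty input: empty report with the header columns
  rep0 <- build_pathway_report(sel[0, ])
  expect_identical(nrow(rep0), 0L)
  expect_true(all(c("pathway_id", "pathway_name", "pair", "cor_dif") %in%
                  names(rep0)))
})

test_that("diffcorr returns a classed fit with working methods", {
  sp <- planted_spec(2, 20, n_per_cond = 120L, seed = 33, n_null_probes = 3)
  ds <- generate_expression(sp)
  fit <- diffcorr(ds$matrix, ds$design, reference = "nonrelapse",
                  pairs = ds$truth[, c("probe_a", "probe_b")])
  expect_s3_class(fit, "diffcorr")
  expect_identical(fit$test, "relapse")
  expect_identical(nrow(fit$deltas), 22L)
  expect_s3_class(fit$stats, "selection_stats")
  expect_identical(sum(fit$deltas$selected), nrow(fit$selected))

  expect_output(print(fit), "Differential correlation")
  s <- summary(fit)
  expect_s3_class(s, "summary.diffcorr")
  expect_output(print(s), "Per-condition pair classification")
  expect_identical(unname(s$class_counts[, "n_samples"]), c(120L, 120L))
  expect_identical(sum(s$class_counts["nonrelapse",
                                      c("coexpressed", "reverse",
                                        "unrelated", "undefined")]), 22L)

  cf <- coef(fit)
  expect_length(cf, 22L)
  expect_named(cf)
  expect_identical(as.data.frame(fit), fit$deltas)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()

  expect_error(diffcorr(ds$matrix, ds$design, reference = "zz",
                        pairs = ds$truth[, c("probe_a", "probe_b")]),
               "not in design")
})

test_that("diffcorr maps pathways to probe pairs and aggregates genes", {
  sp <- planted_spec(1, 8, n_per_cond = 100L, seed = 55, probes_per_gene = 2L)
  ds <- generate_expression(sp)
  kgml_path <- tempfile(fileext = ".xml")
  writeLines(make_kgml_fixture(ds$truth), kgml_path)

  fit <- diffcorr(ds$matrix, ds$design, reference = "nonrelapse",
                  annotation = ds$annotation, pathways = kgml_path)
  # 2 probes per gene -> 4 probe pairs per planted gene pair
  expect_identical(nrow(fit$pairs), 4L * 9L)
  expect_identical(nrow(fit$gene_table), 9L)
  expect_identical(unique(fit$gene_table$n_probe_pairs), 4L)
  # "max" representative carries the largest |cor_dif| of its group
  g1 <- fit$gene_table[1, ]
  grp <- fit$deltas[fit$deltas$gene_a == g1$gene_a, ]
  expect_equal(abs(g1$cor_dif), max(abs(grp$cor_dif)))
  expect_identical(lengths(strsplit(g1$alternate_probe_pairs, ";")), 3L)

  fit_mean <- diffcorr(ds$matrix, ds$design, reference = "nonrelapse",
                       annotation = ds$annotation, pathways = kgml_path,
                       aggregate = "mean")
  gm <- fit_mean$gene_table
  expect_equal(gm$cor_dif_gene[gm$gene_a == g1$gene_a],
               mean(grp$cor_dif))

  expect_error(diffcorr(ds$matrix, ds$design, reference = "nonrelapse",
                        pathways = kgml_path),
               "requires a probe annotation")
})
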