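test_that("fit_line solves the normal equations", {
  f <- fit_line(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$squared_residuals, rep(0, 3))

  # hand-solved normal equations: Sxy=4, Sxx=5
  f2 <- fit_line(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(f2$slope, 0.8)
  expect_equal(f2$intercept, 0.5)
  expect_equal(f2$squared_residuals, c(0.09, 0.81, 0.81, 0.09))

  expect_error(fit_line(c(0, 1), c(0, 1)), "at least 3")
  expect_error(fit_line(1:4, 1:3), "equal length")

  # degenerate: constant x
  fd <- fit_line(rep(2, 5), rnorm(5))
  expect_true(fd$degenerate)
  expect_true(all(is.na(fd$squared_residuals)))

  # independent oracle: lm() on random instances
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 2 * x + rnorm(n)
    f <- fit_line(x, y)
    ref <- lm(y ~ x)
    expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-12)
    expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
    expect_equal(f$squared_residuals, unname(residuals(ref)^2),
                 tolerance = 1e-12)
  }
})

test_that("discard_outliers flags squared residuals beyond mean + k*SD", {
  # perfectly collinear: SD = 0, threshold = 0, nothing strictly exceeds it
  f <- discard_outliers(1:10, 2 * (1:10) + 1)
  expect_true(all(f$keep_mask))
  expect_identical(f$n_used, 10L)

  # 20 on-line points + 1 gross outlier: brute-force oracle
  x <- seq_len(21)
  y <- 2 * x + 1
  y[8] <- y[8] + 100
  fit <- lm(y ~ x)
  sq <- unname(residuals(fit)^2)
  thr <- mean(sq) + 3 * sqrt(mean((sq - mean(sq))^2))
  expect_identical(which(sq > thr), 8L)  # oracle isolates the outlier
  f <- discard_outliers(x, y)
  expect_identical(which(!f$keep_mask), 8L)
  expect_equal(f$threshold, thr)

  # degenerate fit: all kept, threshold undefined
  fd <- discard_outliers(rep(1, 6), rnorm(6))
  expect_true(all(fd$keep_mask))
  expect_true(is.na(fd$threshold))
})

test_that("retention floor caps discards at floor(0.2 * n)", {
  # 4 gross outliers in n=10: never more than floor(0.2*10)=2 removed
  # (mean + 3*SD of squared residuals can flag at most n/10 points, so the
  # cap is a guarantee, not the usual binding constraint, at multiplier 3)
  x <- 1:10
  y <- x
  y[c(2, 5, 7, 9)] <- y[c(2, 5, 7, 9)] + c(50, 60, 70, 80)
  f <- discard_outliers(x, y)
  expect_lte(sum(!f$keep_mask), 2L)
  expect_gte(f$n_used, 8L)

  # cap binds at a lower multiplier: independent brute-force oracle for the
  # flag set, then the cap keeps only the largest-residual discards
  x2 <- seq_len(20)
  y2 <- x2
  y2[c(3, 8, 12, 16, 19)] <- y2[c(3, 8, 12, 16, 19)] + c(11, 12, 13, 14, 15)
  sq <- unname(residuals(lm(y2 ~ x2))^2)
  thr <- mean(sq) + 1 * sqrt(mean((sq - mean(sq))^2))
  flagged <- which(sq > thr)
  expect_gt(length(flagged), 4L)  # oracle flags more than the cap allows
  expected_discard <- flagged[order(-sq[flagged], flagged)][1:4]
  f2 <- discard_outliers(x2, y2, sd_multiplier = 1)
  expect_identical(f2$n_used, 16L)
  expect_identical(which(!f2$keep_mask), sort(expected_discard))

  # property: never below the floor, even at 40% contamination
  set.seed(77)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- rnorm(n); y <- x + rnorm(n, sd = 0.1)
    bad <- sample(n, ceiling(0.4 * n))
    y[bad] <- y[bad] + rnorm(length(bad), 30, 5)
    f <- discard_outliers(x, y)
    expect_lte(sum(!f$keep_mask), floor(0.2 * n))
    expect_gte(f$n_used, ceiling(0.8 * n))
  }
})

test_that("sd_type flag switches between population and sample SD", {
  set.seed(9)
  x <- rnorm(12); y <- x + rnorm(12)
  sq <- fit_line(x, y)$squared_residuals
  f_pop <- discard_outliers(x, y, sd_type = "population")
  f_smp <- discard_outliers(x, y, sd_type = "sample")
  expect_equal(f_pop$threshold, mean(sq) + 3 * sqrt(mean((sq - mean(sq))^2)))
  expect_equal(f_smp$threshold, mean(sq) + 3 * sd(sq))
  expect_gt(f_smp$threshold, f_pop$threshold)
})

test_that("pearson_cor matches the product-moment formula and its symmetries", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1), 1)
  expect_equal(pearson_cor(x, -x), -1)
  # direct formula: Sxy=4, Sxx=Syy=5 -> r = 4/5
  expect_equal(pearson_cor(x, c(1, 3, 2, 4)), 0.8)

  expect_true(is.na(pearson_cor(x, rep(1, 4))))   # constant -> undefined
  expect_true(is.na(pearson_cor(x[1:2], x[1:2]))) # too few points
  expect_error(pearson_cor(1:4, 1:3), "equal length")

  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_identical(pearson_cor(a, b), pearson_cor(b, a))
    # invariant under positive affine transforms
    expect_equal(pearson_cor(2.5 * a + 3, b), pearson_cor(a, b),
                 tolerance = 1e-12)
    expect_equal(pearson_cor(a, 0.1 * b - 7), pearson_cor(a, b),
                 tolerance = 1e-12)
  }
})

test_that("classify_cor uses strict inequalities at +/- threshold", {
  expect_identical(classify_cor(c(0.46, 0.45, 0, -0.45, -0.46, NA)),
                   c("coexpressed", "unrelated", "unrelated", "unrelated",
                     "reverse", "undefined"))
  # the unrelated set is exactly the closed interval [-0.45, 0.45]
  grid <- seq(-0.45, 0.45, length.out = 1001)
  expect_true(all(classify_cor(grid) == "unrelated"))
  eps <- .Machine$double.eps
  expect_identical(classify_cor(0.45 * (1 + 2 * eps)), "coexpressed")
  expect_identical(classify_cor(-0.45 * (1 + 2 * eps)), "reverse")
  # configurable threshold
  expect_identical(classify_cor(0.5, threshold = 0.6), "unrelated")
})

test_that("correlate_pair composes filter, correlation and classification", {
  set.seed(21)
  xy <- rbvn(200, 0.9, mean = 8)
  m <- rbind(pa = xy[, 1], pb = xy[, 2], pc = rep(3, 200))
  colnames(m) <- sprintf("s%03d", 1:200)

  res <- correlate_pair(m, "pa", "pb")
  expect_identical(res$n_total, 200L)
  expect_lt(abs(res$r - 0.9), 0.07)
  expect_identical(res$class, "coexpressed")
  expect_gte(res$n_used, 160L)

  # a missing value in one probe drops that sample pairwise
  m2 <- m; m2["pa", 1] <- NA
  expect_identical(correlate_pair(m2, "pa", "pb")$n_total, 199L)

  # constant partner probe: undefined correlation
  res_c <- correlate_pair(m, "pa", "pc")
  expect_true(is.na(res_c$r))
  expect_identical(res_c$class, "undefined")

  # below the minimum usable sample count: undefined, not estimated
  res_min <- correlate_pair(m, "pa", "pb", samples = colnames(m)[1:8])
  expect_identical(res_min$class, "undefined")
  expect_identical(res_min$n_total, 8L)

  expect_error(correlate_pair(m, "nope", "pb"), "unknown probe")
})

test_that("correlate_pairs equals per-pair calls, in input order", {
  set.seed(4)
  m <- matrix(rnorm(10 * 40, 8), 10, 40,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%02d", 1:40)))
  pairs <- data.frame(probe_a = c("p03", "p01", "p07"),
                      probe_b = c("p04", "p09", "p02"),
                      stringsAsFactors = FALSE)
  got <- correlate_pairs(m, pairs, condition = "c1")
  for (i in 1:3) {
    one <- correlate_pair(m, pairs$probe_a[i], pairs$probe_b[i],
                          condition = "c1")
    expect_equal(got[i, ], one, ignore_attr = TRUE)
  }
  expect_error(correlate_pairs(m, data.frame(probe_a = "p01",
                                             probe_b = "zz")),
               "not in matrix")
})

test_that("clean bivariate data is barely affected by the filter", {
  # Outlier-free n=200. The filter trims the ~2% largest-residual samples.
  # At |rho|=0.8 this shifts r by a tightly concentrated ~0.02 away from
  # zero (the trimmed samples carry a large share of the residual variance),
  # so filtered and raw r agree within 0.05 in >=99% of replicates; at
  # rho=0 the shift is centred on zero but noisier, and the agreement rate
  # drops to ~92%.
  set.seed(42)
  for (rho in c(-0.8, 0, 0.8)) {
    n_rep <- 1000L
    agree <- 0L
    dev <- numeric(n_rep)
    discarded <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      xy <- rbvn(200, rho)
      f <- discard_outliers(xy[, 1], xy[, 2])
      r_raw <- pearson_cor(xy[, 1], xy[, 2])
      r_f <- pearson_cor(xy[f$keep_mask, 1], xy[f$keep_mask, 2])
      dev[i] <- r_f - r_raw
      discarded[i] <- 200L - f$n_used
      agree <- agree + (abs(r_f - r_raw) < 0.05)
    }
    expect_lt(mean(discarded), 8)           # "few points": < 4% on average
    expect_lt(mean(abs(dev)), 0.04)         # small systematic effect
    if (rho == 0) {
      expect_gte(agree, 900L)
      expect_lt(abs(mean(dev)), 0.005)      # no systematic shift at rho=0
    } else {
      expect_gte(agree, 990L)               # within 0.05 in >= 99%
      expect_gt(mean(dev) * sign(rho), 0)   # inflation away from zero
    }
  }
})

test_that("log2 fold change is the difference of condition means", {
  m <- matrix(c(2, 2, 2, 3, 3, 3,
                1, 2, 3, 4, 5, 6), 2, 6, byrow = TRUE,
              dimnames = list(c("pa", "pb"), sprintf("s%d", 1:6)))
  design <- data.frame(sample_id = sprintf("s%d", 1:6),
                       condition = rep(c("ctl", "case"), each = 3))
  expect_equal(log2_fold_change(m, "pa", design, reference = "ctl"), 1)
  expect_equal(log2_fold_change(m, "pb", design, reference = "ctl"),
               mean(c(4, 5, 6)) - mean(c(1, 2, 3)))
  # identical means -> 0; missing values excluded
  m2 <- m; m2["pa", ] <- c(5, NA, 5, 5, 5, NA)
  expect_equal(log2_fold_change(m2, "pa", design, reference = "ctl"), 0)
  m3 <- m; m3["pa", 1:3] <- NA
  expect_warning(fc <- log2_fold_change(m3, "pa", design, reference = "ctl"),
                 "undefined")
  expect_true(is.na(fc))
  expect_error(log2_fold_change(m, "pa", design, reference = "zz"),
               "not in design")
})
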