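test_that("fit_linear matches exact lines and the normal-equations oracle", {
  # exact fits make stats::summary.lm warn about perfect fits; that is the
  # situation under test, not a defect
  f <- suppressWarnings(fit_linear(1:10, 2 * (1:10) + 1))
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(2, 1, 1))

  f3 <- suppressWarnings(fit_linear(c(1, 2, 3), c(-1, -2, -3)))
  expect_equal(c(f3$slope, f3$r_squared), c(-1, 1))

  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    f <- fit_linear(x, y)
    o <- oracle_ols(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  }
  expect_error(fit_linear(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("null regression p-values are uniform", {
  set.seed(33)
  ps <- replicate(300, fit_linear(rnorm(20), rnorm(20))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Bonferroni threshold is alpha/m and scales as 1/m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 500), 1e-4)
  # printed metabolome threshold, to within 1%
  expect_lt(abs(bonferroni_threshold(0.05, 244) - 2.04e-4) / 2.04e-4, 0.01)
  m <- c(10, 100, 1000, 10000)
  expect_equal(diff(log(vapply(m, bonferroni_threshold, 1, alpha = 0.05))) /
                 diff(log(m)), rep(-1, 3))
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("univariate screen preserves order and flags constant columns", {
  set.seed(35)
  w <- runif(30, 1, 8)
  mat <- cbind(up = 10 + 2 * w + rnorm(30, 0, 0.5),
               flat = rnorm(30),
               const = rep(3, 30))
  expect_warning(screen <- univariate_screen(mat, w), "degenerate")
  expect_equal(screen$analyte, c("up", "flat", "const"))
  expect_true(screen$degenerate[3])
  expect_gt(screen$slope[1], 0)

  single <- univariate_screen(mat[, "up", drop = FALSE], w)
  expect_equal(nrow(single), 1)
  expect_error(univariate_screen(mat[1:10, ], w), "match")
})

test_that("volcano merge applies a strict Bonferroni boundary", {
  screen <- data.frame(
    analyte = c("a", "b", "c"),
    slope = 1, intercept = 0, r_squared = 0.5,
    p_value = c(1e-6, 0.05 / 244, 0.5),
    n = 30, degenerate = FALSE)
  lo <- stats::setNames(c(0.2, -0.1, 0.01), c("a", "b", "c"))
  v <- volcano_table(screen, lo, alpha = 0.05, m = 244)
  expect_equal(v$analyte, c("a", "b", "c"))           # sorted by -log10 p
  expect_true(v$passes_bonferroni[v$analyte == "a"])
  expect_false(v$passes_bonferroni[v$analyte == "b"]) # exactly at threshold
  expect_false(v$passes_bonferroni[v$analyte == "c"])
  expect_error(volcano_table(screen, lo[1:2]), "no loading")
})

test_that("best-subset search is exhaustive, monotone and exact on oracles", {
  set.seed(37)
  n <- 60
  y <- rnorm(n)
  x <- cbind(self = y, matrix(rnorm(n * 4), n, 4,
                              dimnames = list(NULL, paste0("z", 1:4))))
  bs <- best_subset(x, y, nvmax = 3, nbest = 5)
  expect_equal(bs$subsets$variables[bs$subsets$size == 1][1], "self")
  expect_equal(bs$subsets$r_squared[bs$subsets$size == 1][1], 1)

  # monotone: best R2 non-decreasing in model size
  best_by_size <- tapply(bs$subsets$r_squared, bs$subsets$size, max)
  expect_true(all(diff(best_by_size) >= -1e-12))

  # orthogonal predictors: subset R2 equals the sum of univariate R2
  xo <- unclass(stats::poly(seq_len(n), 3))  # orthonormal, centred columns
  colnames(xo) <- paste0("o", 1:3)
  yy <- rnorm(n)
  bso <- best_subset(xo, yy, nvmax = 3, nbest = 10)
  r2_uni <- vapply(1:3, function(j) oracle_ols(xo[, j], yy)$r_squared, 1)
  pair <- bso$subsets[bso$subsets$size == 2 &
                        bso$subsets$variables == "o1,o2", "r_squared"]
  expect_equal(pair, sum(r2_uni[1:2]), tolerance = 1e-8)

  # nvmax = 1 ranking equals univariate R2 ranking
  bs1 <- best_subset(x, y, nvmax = 1, nbest = 5)
  r2u <- vapply(seq_len(ncol(x)), function(j) oracle_ols(x[, j], y)$r_squared, 1)
  expect_equal(bs1$subsets$variables,
               colnames(x)[order(-r2u)][1:5])

  expect_error(best_subset(matrix(rnorm(60 * 26), 60, 26,
                                  dimnames = list(NULL, paste0("v", 1:26))),
                           rnorm(60)), "25 predictors")
})

test_that("duplicate columns break ties deterministically", {
  set.seed(39)
  n <- 40
  z <- rnorm(n)
  x <- cbind(a = z, b = z, c = rnorm(n))
  y <- z + rnorm(n, 0, 0.5)
  bs1 <- best_subset(x, y, nvmax = 2, nbest = 3)
  bs2 <- best_subset(x, y, nvmax = 2, nbest = 3)
  expect_identical(bs1$subsets, bs2$subsets)
  expect_equal(bs1$subsets$variables[bs1$subsets$size == 1][1], "a")
})

test_that("top candidate pre-filter ranks by univariate R2", {
  screen <- data.frame(analyte = c("a", "b", "c", "d"),
                       slope = 1, intercept = 0,
                       r_squared = c(0.1, 0.9, 0.5, NA),
                       p_value = 0.01, n = 30,
                       degenerate = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(top_candidates(screen, 2), c("b", "c"))
})
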