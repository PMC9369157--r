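test_that("unit-variance scaling round-trips and drops constant columns", {
  set.seed(41)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc <- uv_scale(x)
  expect_equal(unname(colMeans(sc$x)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(sc$x, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(uv_invert(sc, sc$x), x, tolerance = 1e-10,
               ignore_attr = TRUE)
  # already standardised input is unchanged
  z <- scale(x)[, ]
  expect_equal(uv_scale(z)$x, z, tolerance = 1e-10, ignore_attr = TRUE)
  xc <- cbind(x, d = rep(5, 20))
  expect_warning(sc2 <- uv_scale(xc), "constant")
  expect_equal(sc2$kept, c("a", "b", "c"))
})

test_that("PCA explains collinear data with one component and reconstructs", {
  set.seed(43)
  t <- rnorm(30)
  x <- cbind(t, 2 * t, -t) + 0
  colnames(x) <- paste0("v", 1:3)
  m <- pca_fit(x, k = 1, scale = FALSE)
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-10)

  # duplicate samples share scores
  x2 <- rbind(x, x[1, ])
  m2 <- pca_fit(x2, k = 2, scale = FALSE)
  expect_equal(m2$scores[31, ], m2$scores[1, ], tolerance = 1e-8)

  # full-rank reconstruction is exact
  xr <- matrix(rnorm(50), 10, 5)
  mr <- pca_fit(xr, k = 5, scale = FALSE)
  recon <- mr$scores %*% t(mr$loadings)
  expect_equal(recon, sweep(xr, 2, colMeans(xr)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(pca_fit(xr, k = 10), "exceeds")
})

test_that("Hotelling screen flags about 1% of Gaussian null samples at 99%", {
  set.seed(45)
  rate <- mean(replicate(60, {
    x <- matrix(rnorm(100 * 5), 100, 5)
    mean(hotelling_outliers(pca_fit(x, k = 2), level = 0.99))
  }))
  expect_gt(rate, 0.002)
  expect_lt(rate, 0.03)
})

test_that("OPLS with no orthogonal component equals the PLS-1 oracle", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(15:40, 1); p <- sample(3:12, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- opls_fit(x, y, n_ortho = 0, folds = 0, scale = FALSE)
    expect_equal(m$fitted, oracle_pls1_fitted(x, y), tolerance = 1e-8)
  }
})

test_that("OPLS recovers a one-column linear response and its loading", {
  set.seed(49)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("a", 1:6)))
  y <- 3 * x[, 2]
  # a single predictive component plus enough orthogonal components to
  # strip the y-unrelated X-variation reproduces an exact linear response
  m <- opls_fit(x, y, n_ortho = 5, folds = 0)
  expect_equal(m$r2y, 1, tolerance = 1e-8)
  expect_equal(which.max(abs(m$loadings$loading_pq1)), 2L)
})

test_that("orthogonal scores are uncorrelated with y and with the predictive score", {
  set.seed(51)
  x <- matrix(rnorm(50 * 20), 50, 20)
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(50, 0, 0.5)
  m <- opls_fit(x, y, n_ortho = 2, folds = 0)
  yc <- y - mean(y)
  for (a in seq_len(ncol(m$scores_ortho))) {
    expect_lt(abs(sum(m$scores_ortho[, a] * yc)), 1e-8)
  }
})

test_that("OPLS prediction returns fitted values on training data", {
  set.seed(53)
  x <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("m", 1:8)))
  y <- x[, 1] - x[, 3] + rnorm(40, 0, 0.3)
  m <- opls_fit(x, y, n_ortho = 1, folds = 0)
  expect_equal(predict(m, x), m$fitted, tolerance = 1e-10)
  # constant row predicts near the training mean
  xc <- matrix(colMeans(x), 1, 8, dimnames = list(NULL, colnames(x)))
  expect_equal(unname(predict(m, xc)), mean(y), tolerance = 1e-8)
  expect_error(predict(m, x[, 1:3]), "lacks column")
})

test_that("Q2 behaves at its limits and never exceeds R2Y", {
  set.seed(55)
  x <- matrix(rnorm(70 * 10), 70, 10)
  y_clean <- 2 * x[, 1] + x[, 2]
  m_clean <- opls_fit(x, y_clean, n_ortho = 2)
  expect_gt(m_clean$q2, 0.95)

  for (i in 1:10) {
    xi <- matrix(rnorm(40 * 8), 40, 8)
    yi <- xi[, 1] + rnorm(40)
    mi <- opls_fit(xi, yi, n_ortho = 1)
    expect_lte(mi$q2, mi$r2y)
  }

  set.seed(56)
  q2_null <- replicate(40, {
    xn <- matrix(rnorm(40 * 8), 40, 8)
    q2_cross_validation(xn, rnorm(40), folds = 7, n_ortho = 1)$q2
  })
  expect_lt(mean(q2_null), 0)
})

test_that("permuted responses destroy predictive power", {
  set.seed(57)
  x <- matrix(rnorm(60 * 15), 60, 15)
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(60, 0, 0.4)
  q2_perm <- replicate(100, {
    q2_cross_validation(x, sample(y), folds = 7, n_ortho = 1)$q2
  })
  expect_gte(sum(q2_perm <= 0), 90)
})

test_that("CV-ANOVA separates signal from noise", {
  set.seed(59)
  x <- matrix(rnorm(80 * 12), 80, 12)
  y <- 2 * x[, 1] + x[, 2] + rnorm(80, 0, 0.3)
  cv <- q2_cross_validation(x, y, folds = 7, n_ortho = 1)
  expect_lt(cv_anova(cv)$p_value, 1e-6)

  # identical y and prediction: p in the zero limit
  cv0 <- structure(list(y_cv = y, press = 0, press0 = sum((y - mean(y))^2),
                        tss = sum((y - mean(y))^2), fold = rep(1:7, len = 80),
                        folds = 7, n_components = 2, q2 = 1),
                   class = "opls_cv")
  expect_equal(cv_anova(cv0)$p_value, 0)

  # null data: p is conservative (never anti-conservative)
  set.seed(60)
  ps <- replicate(50, {
    xn <- matrix(rnorm(40 * 8), 40, 8)
    cv_anova(q2_cross_validation(xn, rnorm(40), folds = 7, n_ortho = 1))$p_value
  })
  expect_lt(mean(ps < 0.05), 0.075)
})

test_that("fold assignment is deterministic and guarded", {
  expect_identical(fold_assignment(14, 7), rep(1:7, 2))
  f1 <- fold_assignment(30, 7, cv_seed = 5)
  f2 <- fold_assignment(30, 7, cv_seed = 5)
  expect_identical(f1, f2)
  expect_error(fold_assignment(10, 7), "fewer than 2")
})

test_that("score clustering recovers separated groups and degenerate cuts", {
  set.seed(61)
  scores <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                  matrix(rnorm(40, 5, 0.2), 20, 2))
  cl <- cluster_scores(scores, k = 2)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_false(cl[1] == cl[40])

  expect_equal(sort(unique(cluster_scores(scores, k = 40))), 1:40)

  # duplicated dataset co-clusters duplicates
  dup <- rbind(scores, scores)
  cld <- cluster_scores(dup, k = 2)
  expect_equal(cld[1:40], cld[41:80], ignore_attr = TRUE)
})

test_that("restricted weight windows degrade weight discrimination", {
  cfg <- generator_config(accession_sd = 0.3, rng_seed = 71)
  cohort <- simulate_cohort(cfg)
  full <- opls_fit(cohort$metabolome, cohort$seeds$weight_mg, n_ortho = 1)
  win <- cohort$seeds$weight_mg >= 3.5 & cohort$seeds$weight_mg <= 5.5
  sub <- opls_fit(cohort$metabolome[win, ], cohort$seeds$weight_mg[win],
                  n_ortho = 1)
  # predictive discrimination of weight degrades on the narrow window
  expect_lt(sub$q2, full$q2)
})
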