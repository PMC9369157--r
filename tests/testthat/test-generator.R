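test_that("weights respect accession ranges and are reproducible", {
  acc <- accession_table()
  expect_equal(nrow(acc), 8)
  jem <- acc[acc$accession_no == 738, ]
  expect_equal(c(jem$weight_min, jem$weight_max), c(1.1, 6.3))

  set.seed(7); w1 <- sample_weights(jem, 500)
  set.seed(7); w2 <- sample_weights(jem, 500)
  expect_identical(w1, w2)
  expect_true(all(w1 >= 1.1 & w1 <= 6.3))
  expect_length(sample_weights(jem, 0), 0)
})

test_that("elemental mode embeds the configured linear allometry", {
  cfg <- generator_config()
  set.seed(11)
  w <- runif(400, 1, 8)

  # noise-free limit: exactly linear, R2 = 1
  cfg0 <- generator_config(target_r2_n = 1 - 1e-12, target_r2_h = 1 - 1e-12,
                           sd_c = 0, sd_s = 0)
  e0 <- simulate_elemental(w, cfg0)
  f0 <- fit_linear(w, e0$pct_n)
  expect_equal(f0$slope, cfg$slope_n, tolerance = 1e-4)
  expect_gt(f0$r_squared, 0.999)

  # defaults: slope recovery within the 95% CI
  e <- simulate_elemental(w, cfg)
  fn <- fit_linear(w, e$pct_n)
  expect_true(fn$slope_lo <= cfg$slope_n && cfg$slope_n <= fn$slope_hi)
  fh <- fit_linear(w, e$pct_h)
  expect_true(fh$slope_lo <= cfg$slope_h && cfg$slope_h <= fh$slope_hi)

  expect_error(generator_config(target_r2_n = 1.2), "R2")
})

test_that("noise calibration hits the target R2 on average", {
  cfg <- generator_config()
  set.seed(13)
  r2 <- replicate(50, {
    w <- as.vector(sapply(seq_len(8), function(i)
      sample_weights(accession_table()[i, ], 20)))
    e <- simulate_elemental(w, cfg)
    fit_linear(w, e$pct_n)$r_squared
  })
  expect_lt(abs(mean(r2) - cfg$target_r2_n), 0.05)
})

test_that("biochemical mode is exactly invertible and lipid decays with weight", {
  cfg <- generator_config(mode = "biochemical")
  w <- seq(1, 6, length.out = 30)
  bio <- simulate_biochemical(w, cfg)
  expect_true(all(diff(bio$true_w_lip) < 0))
  expect_equal(lipid_decay(100, cfg), cfg$lipid_min, tolerance = 1e-6)
  k0 <- generator_config(lipid_rate = 0)
  expect_equal(lipid_decay(w, k0), rep(k0$lipid_max, length(w)))

  seeds <- data.frame(seed_id = sprintf("s%02d", seq_along(w)), bio)
  comp <- compose_seeds(seeds)
  expect_lt(max(abs(comp$w_lip - bio$true_w_lip)), 1e-6)
  expect_lt(max(abs(comp$w_carb - bio$true_w_carb)), 1e-6)
  expect_lt(max(abs(comp$x_lipid_h - bio$true_x_lipid_h)), 1e-6)

  expect_error(simulate_biochemical(w, generator_config(lipid_max = 0.9)),
               "\\[0, 1\\]")
})

test_that("isotope simulation follows the mass balance and its noise target", {
  cfg <- generator_config()
  x <- seq(0.05, 0.5, length.out = 160)
  # noise-free: points on the scenario line
  set.seed(5)
  cfg_pure <- generator_config(target_r2_d2h = 1 - 1e-12)
  iso0 <- simulate_isotopes(x, cfg_pure)
  pred <- predict_seed_delta2h(x, isotope_scenario(cfg$scenario_name))
  expect_equal(iso0$d2h, pred, tolerance = 1e-3)

  # mean achieved R2 near target
  set.seed(6)
  r2 <- replicate(50, fit_linear(x, simulate_isotopes(x, cfg)$d2h)$r_squared)
  expect_lt(abs(mean(r2) - cfg$target_r2_d2h), 0.05)

  # other deltas carry no weight signal
  set.seed(8)
  w <- runif(160, 1, 8)
  iso <- simulate_isotopes(x, cfg)
  expect_lt(fit_linear(w, iso$d13c)$r_squared, 0.1)
})

test_that("delta-2H declines with weight when lipid decays with weight", {
  cohort <- simulate_cohort(generator_config(mode = "biochemical",
                                             rng_seed = 404))
  f <- fit_linear(cohort$seeds$weight_mg, cohort$seeds$d2h)
  expect_lt(f$slope, 0)
})

test_that("metabolome classes carry their designed weight signs", {
  cfg <- generator_config()
  set.seed(21)
  w <- runif(160, 1, 8)
  acc <- sample(letters[1:8], 160, replace = TRUE)
  met <- simulate_metabolome(w, acc, cfg)
  expect_equal(ncol(met$matrix), 244)
  expect_true(all(met$matrix >= 0))
  expect_equal(nrow(met$annotations), 244)

  screen <- univariate_screen(met$matrix, w)
  merged <- merge(screen, met$annotations, by = "analyte")
  pos <- merged[merged$weight_sign == 1, ]
  neg <- merged[merged$weight_sign == -1, ]
  expect_gt(mean(pos$slope > 0), 0.95)
  expect_gt(mean(neg$slope < 0), 0.95)

  # paired amino acid / degradation product: opposite weight trends
  pairs <- merged[!is.na(merged$pair_id), ]
  for (pid in unique(pairs$pair_id)) {
    pr <- pairs[pairs$pair_id == pid, ]
    expect_equal(nrow(pr), 2)
    expect_lt(prod(pr$slope), 0)
  }
})

test_that("cohorts are deterministic in the seed and structurally complete", {
  cfg <- generator_config(n_seeds_per_accession = 3, rng_seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$seeds, c2$seeds)
  expect_identical(c1$metabolome, c2$metabolome)
  expect_equal(nrow(c1$seeds), 24)
  expect_equal(length(unique(c1$seeds$accession)), 8)

  c3 <- simulate_cohort(generator_config(n_seeds_per_accession = 1))
  expect_equal(nrow(c3$seeds), 8)
})

test_that("cohort files round-trip through the standard readers", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(generator_config(n_seeds_per_accession = 2,
                                             rng_seed = 3))
  m1 <- write_cohort(cohort, dir)
  seeds <- read_seed_table(file.path(dir, "seeds.csv"))
  expect_equal(seeds$weight_mg, cohort$seeds$weight_mg, tolerance = 1e-12)
  met <- read_metabolome(file.path(dir, "metabolome.tsv"))
  expect_equal(dim(met), dim(cohort$metabolome))
  expect_equal(unname(met[1, 1]), unname(cohort$metabolome[1, 1]),
               tolerance = 1e-10)
  # identical seed, identical checksums
  dir2 <- withr::local_tempdir()
  m2 <- write_cohort(simulate_cohort(cohort$config), dir2)
  expect_equal(m1$checksums, m2$checksums)
})
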