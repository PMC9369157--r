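#' Accession panel with natural seed weight ranges
#'
#' The eight barrel medic (Medicago truncatula) core-collection accessions
#' the analyses cover, with their natural single-seed weight ranges in mg.
#'
#' @return A data.frame with columns `name`, `accession_no`, `weight_min`,
#'   `weight_max`.
#' @export
accession_table <- function() {
  df <- data.frame(
    name = base::c("Jemalong A17", "DZA045-6", "DZA315-16", "ESP105-L",
                   "F83005-5", "DZA012-J", "SA028064", "SA022322"),
    accession_no = base::c(738L, 736L, 734L, 544L, 530L, 368L, 174L, 163L),
    weight_min = base::c(1.1, 1.8, 1.9, 2.3, 2.0, 1.0, 2.0, 2.0),
    weight_max = base::c(6.3, 6.4, 6.1, 8.6, 6.7, 5.1, 7.2, 6.2),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$weight_min > 0), all(df$weight_min < df$weight_max))
  df
}

#' Configuration of the synthetic seed-cohort generator
#'
#' Collects every knob of the generator with defaults matching the
#' statistical structure the analyses assume: linear elemental allometry
#' (+0.17 %N/mg with R2 0.36, -0.14 %H/mg), delta-2H produced by the
#' isotope mass balance plus noise calibrated to R2 0.38 against the lipid
#' H mole fraction, and a 244-analyte metabolome with weight-correlated
#' classes and paired amino-acid / degradation-product columns.
#'
#' @param n_seeds_per_accession Seeds per accession (default 20).
#' @param rng_seed Integer seed controlling all randomness.
#' @param mode `"elemental"` (percent compositions drawn directly around
#'   the linear allometry) or `"biochemical"` (latent component fractions
#'   drawn first and mapped through the exact mixing model, so inversion
#'   recovery is exact).
#' @param slope_n,slope_h Allometric slopes in raw percent per mg.
#' @param intercept_n,intercept_h Raw percent at 1 mg minus one slope unit;
#'   defaults put %N near 6 and %H near 7 at 1 mg (calibration choices).
#' @param mean_c,sd_c,mean_s,sd_s Raw percent mean/SD for C and S.
#' @param target_r2_n,target_r2_h Target R2 of the %N and %H regressions
#'   on weight; noise SDs are calibrated as
#'   `sd^2 = slope^2 * Var(w) * (1 - R2) / R2`.
#' @param w_carb,w_alb Constant carbohydrate and albumin fractions
#'   (biochemical mode).
#' @param lipid_max,lipid_min,lipid_rate Lipid fraction decay with weight,
#'   `w_lip(w) = lipid_min + (lipid_max - lipid_min) * exp(-rate*(w - 1))`.
#' @param scenario_name Isotope scenario used to generate delta-2H.
#' @param target_r2_d2h Target R2 of delta-2H on the lipid H mole fraction.
#' @param mean_d13c,sd_d13c,mean_d15n,sd_d15n,mean_d34s,sd_d34s Per-mil
#'   means/SDs of the weight-independent isotope deltas.
#' @param n_analytes Number of metabolome columns (default 244).
#' @param class_counts Named integer vector of analyte counts per class;
#'   classes `hexose`, `amino_acid`, `nucleoside` load positively on
#'   weight, `disaccharide`, `fatty_acid`, `organic_acid`,
#'   `degradation_product` negatively, `null` not at all. Must sum to
#'   `n_analytes`.
#' @param n_pairs Number of amino-acid / degradation-product pairs (taken
#'   from the `amino_acid` and `degradation_product` budgets).
#' @param effect Log-intensity change per mg of weight for non-null
#'   analytes (0 gives an all-null matrix for type-I calibration).
#' @param noise_sd Log-intensity Gaussian noise SD.
#' @param baseline_range Range of per-analyte baseline log-intensities.
#' @param accession_sd SD of per-accession log-intensity offsets
#'   (near-zero by default; raise to study accession structure).
#' @param small_seed_s_bump Optional raw %S addition below 2 mg (off by
#'   default).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_seeds_per_accession = 20,
                             rng_seed = 20220730,
                             mode = base::c("elemental", "biochemical"),
                             slope_n = 0.17, slope_h = -0.14,
                             intercept_n = 5.83, intercept_h = 7.14,
                             mean_c = 43.5, sd_c = 0.5,
                             mean_s = 0.33, sd_s = 0.04,
                             target_r2_n = 0.36, target_r2_h = 0.36,
                             w_carb = 0.37, w_alb = 0.13,
                             lipid_max = 0.22, lipid_min = 0.08,
                             lipid_rate = 0.4,
                             scenario_name = "a",
                             target_r2_d2h = 0.38,
                             mean_d13c = -28, sd_d13c = 1,
                             mean_d15n = 1, sd_d15n = 1,
                             mean_d34s = 4, sd_d34s = 1.5,
                             n_analytes = 244,
                             class_counts = NULL,
                             n_pairs = 5,
                             effect = 0.25,
                             noise_sd = 0.30,
                             baseline_range = base::c(8, 12),
                             accession_sd = 0.02,
                             small_seed_s_bump = 0) {
  mode <- match.arg(mode)
  for (r2 in base::c(target_r2_n, target_r2_h, target_r2_d2h))
    if (r2 <= 0 || r2 >= 1) stop("target R2 values must lie in (0, 1)")
  if (is.null(class_counts)) {
    class_counts <- base::c(hexose = 6L, amino_acid = 15L, nucleoside = 2L,
                            disaccharide = 4L, fatty_acid = 3L,
                            organic_acid = 5L, degradation_product = n_pairs,
                            null = 0L)
    class_counts[["null"]] <- n_analytes - sum(class_counts)
  }
  if (sum(class_counts) != n_analytes)
    stop("class_counts must sum to n_analytes")
  if (any(class_counts < 0)) stop("class_counts must be >= 0")
  if (n_pairs > class_counts[["amino_acid"]] ||
      n_pairs > class_counts[["degradation_product"]])
    stop("n_pairs exceeds the amino_acid or degradation_product budget")
  cfg <- list(
    n_seeds_per_accession = n_seeds_per_accession, rng_seed = rng_seed,
    mode = mode,
    slope_n = slope_n, slope_h = slope_h,
    intercept_n = intercept_n, intercept_h = intercept_h,
    mean_c = mean_c, sd_c = sd_c, mean_s = mean_s, sd_s = sd_s,
    target_r2_n = target_r2_n, target_r2_h = target_r2_h,
    w_carb = w_carb, w_alb = w_alb,
    lipid_max = lipid_max, lipid_min = lipid_min, lipid_rate = lipid_rate,
    scenario_name = scenario_name, target_r2_d2h = target_r2_d2h,
    mean_d13c = mean_d13c, sd_d13c = sd_d13c,
    mean_d15n = mean_d15n, sd_d15n = sd_d15n,
    mean_d34s = mean_d34s, sd_d34s = sd_d34s,
    n_analytes = n_analytes, class_counts = class_counts, n_pairs = n_pairs,
    effect = effect, noise_sd = noise_sd, baseline_range = baseline_range,
    accession_sd = accession_sd, small_seed_s_bump = small_seed_s_bump
  )
  structure(cfg, class = "generator_config")
}

#' Noise SD achieving a target regression R2
#'
#' For `y = signal + noise`, `R2 = Var(signal) / (Var(signal) + sd^2)` in
#' expectation, so `sd = sqrt(Var(signal) * (1 - R2) / R2)`.
#'
#' @param signal The noise-free signal values.
#' @param target_r2 Target R2 in (0, 1).
#' @return The calibrated noise SD.
#' @export
calibrate_noise_sd <- function(signal, target_r2) {
  if (target_r2 <= 0 || target_r2 >= 1) stop("target R2 must lie in (0, 1)")
  sqrt(stats::var(signal) * (1 - target_r2) / target_r2)
}

#' Draw seed weights for one accession
#'
#' Weights follow a Beta(2, 2) rescaled to the accession's natural range:
#' mild central tendency, no edge pile-up, support exactly the recorded
#' range.
#'
#' @param spec One row of [accession_table()] (a list/data.frame row with
#'   `weight_min` and `weight_max`).
#' @param n Number of seeds.
#' @return Numeric vector of weights in mg.
#' @export
sample_weights <- function(spec, n) {
  if (n == 0) return(numeric(0))
  spec$weight_min + (spec$weight_max - spec$weight_min) * stats::rbeta(n, 2, 2)
}

#' Simulate raw elemental percent compositions along the allometry
#'
#' Elemental mode: `%N = intercept_n + slope_n * w + eps`, `%H =
#' intercept_h + slope_h * w + eps`, with C and S drawn around constant
#' means; the N and H noise SDs are calibrated against the realised weight
#' variance so the weight regressions achieve the target R2 on average.
#'
#' @param weights Seed weights in mg.
#' @param config A [generator_config()].
#' @return A data.frame with columns `pct_c`, `pct_n`, `pct_s`, `pct_h`
#'   (raw percent, before water/mineral correction).
#' @export
simulate_elemental <- function(weights, config = generator_config()) {
  n <- length(weights)
  mu_n <- config$intercept_n + config$slope_n * weights
  mu_h <- config$intercept_h + config$slope_h * weights
  sd_n <- calibrate_noise_sd(mu_n, config$target_r2_n)
  sd_h <- calibrate_noise_sd(mu_h, config$target_r2_h)
  pct_s <- config$mean_s + stats::rnorm(n, 0, config$sd_s)
  if (config$small_seed_s_bump > 0)
    pct_s <- pct_s + ifelse(weights < 2, config$small_seed_s_bump, 0)
  data.frame(
    pct_c = pmax(config$mean_c + stats::rnorm(n, 0, config$sd_c), 0),
    pct_n = pmax(mu_n + stats::rnorm(n, 0, sd_n), 0),
    pct_s = pmax(pct_s, 0),
    pct_h = pmax(mu_h + stats::rnorm(n, 0, sd_h), 0)
  )
}

#' Latent lipid fraction decay with seed weight
#'
#' `w_lip(w) = lipid_min + (lipid_max - lipid_min) * exp(-rate * (w - 1))`:
#' small seeds are lipid-rich, decaying towards `lipid_min` in large seeds.
#'
#' @param weights Seed weights in mg.
#' @param config A [generator_config()].
#' @return Lipid mass fractions.
#' @export
lipid_decay <- function(weights, config = generator_config()) {
  config$lipid_min +
    (config$lipid_max - config$lipid_min) *
      exp(-config$lipid_rate * (weights - 1))
}

#' Simulate latent biochemical composition and exact elemental percents
#'
#' Biochemical mode: carbohydrate and albumin fractions are constant, the
#' lipid fraction decays with weight, and S-poor proteins plus other
#' nitrogenous compounds take the remainder so fractions sum to one.
#' Elemental percents are obtained through the exact forward mixing model
#' and scaled back to raw (whole-seed) percent by the correction divisor,
#' so that correct-then-invert recovers the latent truth exactly.
#'
#' @param weights Seed weights in mg.
#' @param config A [generator_config()].
#' @param ref A [component_reference()] matrix.
#' @param policy A [correction_policy()].
#' @return A data.frame with latent fractions (`true_w_carb`, `true_w_alb`,
#'   `true_w_spp`, `true_w_lip`, `true_x_lipid_h`) and raw percents
#'   (`pct_c`, `pct_n`, `pct_s`, `pct_h`).
#' @export
simulate_biochemical <- function(weights, config = generator_config(),
                                 ref = component_reference(),
                                 policy = correction_policy()) {
  w_lip <- lipid_decay(weights, config)
  w_spp <- 1 - config$w_carb - config$w_alb - w_lip
  if (any(w_lip < 0 | w_lip > 1) || any(w_spp < 0 | w_spp > 1))
    stop("biochemical-mode fractions leave [0, 1]; adjust lipid/carb/alb parameters")
  out <- lapply(seq_along(weights), function(i) {
    bio <- biochemical_composition(config$w_carb, config$w_alb,
                                   w_spp[i], w_lip[i])
    e <- forward_composition(bio, ref)
    base::c(true_w_carb = config$w_carb, true_w_alb = config$w_alb,
            true_w_spp = w_spp[i], true_w_lip = w_lip[i],
            true_x_lipid_h = lipid_h_mole_fraction(bio, ref),
            pct_c = e[["c"]] * policy$divisor * 100,
            pct_n = e[["n"]] * policy$divisor * 100,
            pct_s = e[["s"]] * policy$divisor * 100,
            pct_h = e[["h"]] * policy$divisor * 100)
  })
  as.data.frame(do.call(rbind, out))
}

#' Simulate isotope deltas for a cohort
#'
#' delta-2H is the isotope mass-balance prediction at each seed's lipid H
#' mole fraction plus Gaussian noise calibrated so the regression of
#' delta-2H on the mole fraction achieves the target R2; delta-13C,
#' delta-15N and delta-34S are weight-independent draws around their
#' configured means.
#'
#' @param x_lipid_h Lipid H mole fraction per seed.
#' @param config A [generator_config()].
#' @param scenario An [isotope_scenario()]; defaults to the configured one.
#' @param constants A [fractionation_constants()].
#' @return A data.frame with columns `d13c`, `d15n`, `d34s`, `d2h`
#'   (per mil).
#' @export
simulate_isotopes <- function(x_lipid_h, config = generator_config(),
                              scenario = NULL,
                              constants = fractionation_constants()) {
  if (is.null(scenario)) scenario <- isotope_scenario(config$scenario_name)
  n <- length(x_lipid_h)
  pred <- predict_seed_delta2h(x_lipid_h, scenario, constants)
  sd_d2h <- if (stats::var(pred) > 0)
    calibrate_noise_sd(pred, config$target_r2_d2h) else 0
  data.frame(
    d13c = stats::rnorm(n, config$mean_d13c, config$sd_d13c),
    d15n = stats::rnorm(n, config$mean_d15n, config$sd_d15n),
    d34s = stats::rnorm(n, config$mean_d34s, config$sd_d34s),
    d2h = pred + stats::rnorm(n, 0, sd_d2h)
  )
}

#' Simulate a normalised single-seed metabolome
#'
#' Log-intensities follow `baseline + sign * effect * (w - mean(w)) +
#' accession offset + noise`, exponentiated to nonnegative intensities
#' (already normalised to internal standard and seed weight, as the
#' pipeline assumes). Hexoses, amino acids and nucleosides rise with
#' weight; disaccharides, fatty acids, organic acids and amino-acid
#' degradation products fall; null analytes carry no weight signal. The
#' first `n_pairs` amino acids are paired with a degradation product of
#' opposite sign (`pair_id` links them).
#'
#' @param weights Seed weights in mg.
#' @param accessions Accession label per seed (for the accession offset).
#' @param config A [generator_config()].
#' @return A list with `matrix` (seeds x analytes, named columns) and
#'   `annotations` (data.frame: `analyte`, `class`, `weight_sign`,
#'   `pair_id`).
#' @export
simulate_metabolome <- function(weights, accessions,
                                config = generator_config()) {
  counts <- config$class_counts
  classes <- rep(names(counts), counts)
  m <- length(classes)
  sign_of <- base::c(hexose = 1, amino_acid = 1, nucleoside = 1,
                     disaccharide = -1, fatty_acid = -1, organic_acid = -1,
                     degradation_product = -1, null = 0)
  signs <- unname(sign_of[classes])
  analyte <- sprintf("%s_%02d", classes,
                     stats::ave(seq_len(m), classes, FUN = seq_along))
  pair_id <- rep(NA_integer_, m)
  if (config$n_pairs > 0) {
    aa_idx <- which(classes == "amino_acid")[seq_len(config$n_pairs)]
    deg_idx <- which(classes == "degradation_product")[seq_len(config$n_pairs)]
    pair_id[aa_idx] <- seq_len(config$n_pairs)
    pair_id[deg_idx] <- seq_len(config$n_pairs)
  }
  n <- length(weights)
  baseline <- stats::runif(m, config$baseline_range[1], config$baseline_range[2])
  acc_levels <- unique(accessions)
  acc_offset <- stats::setNames(
    stats::rnorm(length(acc_levels), 0, config$accession_sd), acc_levels)
  wc <- weights - mean(weights)
  logI <- outer(rep(1, n), baseline) +
    outer(wc, signs * config$effect) +
    matrix(acc_offset[accessions], n, m) +
    matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  mat <- exp(logI)
  colnames(mat) <- analyte
  list(
    matrix = mat,
    annotations = data.frame(analyte = analyte, class = classes,
                             weight_sign = signs, pair_id = pair_id,
                             stringsAsFactors = FALSE)
  )
}

#' Simulate a full synthetic seed cohort
#'
#' Draws weights for every accession, generates elemental composition in
#' the configured mode, derives each seed's biochemical composition and
#' lipid H mole fraction (the exact latent truth in biochemical mode; the
#' mass-balance inversion of the generated percents in elemental mode),
#' simulates isotope deltas and the metabolome. Fully reproducible from
#' `config$rng_seed`; the caller's RNG state is restored on exit.
#'
#' @param config A [generator_config()].
#' @param ref A [component_reference()] matrix.
#' @param policy A [correction_policy()].
#' @return A list of class `seed_cohort`: `seeds` (one row per seed),
#'   `metabolome` (seeds x analytes matrix), `annotations`, `config`.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_seeds_per_accession = 2))
#' dim(cohort$metabolome)
#' @export
simulate_cohort <- function(config = generator_config(),
                            ref = component_reference(),
                            policy = correction_policy()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)

  acc <- accession_table()
  seeds <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
    w <- sample_weights(acc[i, ], config$n_seeds_per_accession)
    if (length(w) == 0) return(NULL)
    data.frame(accession = acc$name[i], accession_no = acc$accession_no[i],
               weight_mg = w, stringsAsFactors = FALSE)
  }))
  n <- nrow(seeds)
  seeds$seed_id <- sprintf("seed_%03d", seq_len(n))
  seeds <- seeds[, base::c("seed_id", "accession", "accession_no", "weight_mg")]

  if (config$mode == "biochemical") {
    bio <- simulate_biochemical(seeds$weight_mg, config, ref, policy)
    seeds <- cbind(seeds, bio)
  } else {
    elem <- simulate_elemental(seeds$weight_mg, config)
    comp <- compose_seeds(cbind(seeds, elem), ref = ref, policy = policy)
    seeds <- cbind(seeds, elem,
                   data.frame(true_w_carb = comp$w_carb,
                              true_w_alb = comp$w_alb,
                              true_w_spp = comp$w_spp,
                              true_w_lip = comp$w_lip,
                              true_x_lipid_h = comp$x_lipid_h))
  }
  iso <- simulate_isotopes(seeds$true_x_lipid_h, config)
  seeds <- cbind(seeds, iso)
  met <- simulate_metabolome(seeds$weight_mg, seeds$accession, config)
  rownames(met$matrix) <- seeds$seed_id
  structure(
    list(seeds = seeds, metabolome = met$matrix,
         annotations = met$annotations, config = config),
    class = "seed_cohort"
  )
}
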