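#' Read a per-seed elemental table
#'
#' CSV with named columns `seed_id`, `accession`, `weight_mg`, `pct_c`,
#' `pct_n`, `pct_s`, `pct_h` (case-insensitive; raw percent by weight).
#' Headers are matched by name, never by position; values use '.' as the
#' decimal separator.
#'
#' @param path CSV file path.
#' @return A data.frame with the canonical lower-case column names.
#' @export
read_seed_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- base::c("seed_id", "weight_mg", "pct_c", "pct_n", "pct_s", "pct_h")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("seed table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a seeds x analytes metabolite matrix
#'
#' TSV with seeds as rows; first column `seed_id`, remaining columns one
#' analyte each (normalised intensities).
#'
#' @param path TSV file path.
#' @return A numeric matrix with seed_id rownames.
#' @export
read_metabolome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "seed_id") stop("first metabolome column must be seed_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$seed_id
  if (any(mat < 0)) stop("metabolite intensities must be nonnegative")
  mat
}

#' Derive biochemical composition for every seed in a table
#'
#' The composition leg of the pipeline: raw percents are converted to
#' fractions, water/mineral-corrected, inverted through the nonnegative
#' mass balance, and the lipid hydrogen mole fraction is computed.
#'
#' @param seeds A data.frame as from [read_seed_table()] (needs `pct_c`,
#'   `pct_n`, `pct_s`, `pct_h`; `seed_id` used in error messages).
#' @param ref A [component_reference()] matrix.
#' @param policy A [correction_policy()].
#' @return A data.frame with one row per seed: `seed_id`, component
#'   fractions `w_carb`, `w_alb`, `w_spp`, `w_lip`, `total`, per-element
#'   residuals `resid_c` .. `resid_h`, and `x_lipid_h`.
#' @export
compose_seeds <- function(seeds, ref = component_reference(),
                          policy = correction_policy()) {
  if (nrow(seeds) == 0) {
    return(data.frame(seed_id = character(0), w_carb = numeric(0),
                      w_alb = numeric(0), w_spp = numeric(0),
                      w_lip = numeric(0), total = numeric(0),
                      resid_c = numeric(0), resid_n = numeric(0),
                      resid_s = numeric(0), resid_h = numeric(0),
                      x_lipid_h = numeric(0)))
  }
  ids <- if ("seed_id" %in% names(seeds)) seeds$seed_id
         else sprintf("row_%d", seq_len(nrow(seeds)))
  rows <- lapply(seq_len(nrow(seeds)), function(i) {
    raw <- elemental_composition(seeds$pct_c[i] / 100, seeds$pct_n[i] / 100,
                                 seeds$pct_s[i] / 100, seeds$pct_h[i] / 100)
    corr <- correct_composition(raw, policy, seed_id = ids[i])
    bio <- suppressWarnings(invert_composition(corr, ref))
    x <- if (bio$total > 0) lipid_h_mole_fraction(bio, ref) else NA_real_
    data.frame(seed_id = ids[i],
               w_carb = bio$fractions[["carbohydrate"]],
               w_alb = bio$fractions[["albumin"]],
               w_spp = bio$fractions[["s_poor_protein_other"]],
               w_lip = bio$fractions[["lipid"]],
               total = bio$total,
               resid_c = bio$residual[["c"]], resid_n = bio$residual[["n"]],
               resid_s = bio$residual[["s"]], resid_h = bio$residual[["h"]],
               x_lipid_h = x)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predicted-versus-observed delta-2H table and scenario lines
#'
#' The isotope leg: for every seed, the lipid H mole fraction is paired
#' with its observed delta-2H and the mass-balance predictions under the
#' three leaf/pod water scenarios; the observed-on-x regression summarises
#' how much delta-2H variance lipid content explains.
#'
#' @param x_lipid_h Lipid H mole fraction per seed.
#' @param observed_d2h Observed delta-2H per seed, in per mil.
#' @param constants A [fractionation_constants()].
#' @return A list: `table` (x, observed, predicted_a/b/c), `regression`
#'   ([fit_linear()] of observed on x), `lines` (scenario lines on a
#'   0..1 grid).
#' @export
isotope_table <- function(x_lipid_h, observed_d2h,
                          constants = fractionation_constants()) {
  if (length(x_lipid_h) != length(observed_d2h))
    stop("x and observed delta-2H must have equal length")
  scen <- lapply(base::c(a = "a", b = "b", c = "c"), isotope_scenario)
  tab <- data.frame(
    x = x_lipid_h, observed = observed_d2h,
    predicted_a = predict_seed_delta2h(x_lipid_h, scen$a, constants),
    predicted_b = predict_seed_delta2h(x_lipid_h, scen$b, constants),
    predicted_c = predict_seed_delta2h(x_lipid_h, scen$c, constants)
  )
  reg <- if (length(x_lipid_h) >= 3 && stats::var(x_lipid_h) > 0)
    fit_linear(x_lipid_h, observed_d2h) else NULL
  lines <- lapply(scen, scenario_line, constants = constants)
  list(table = tab, regression = reg, lines = lines)
}

#' Full metabolome statistics leg
#'
#' Runs the univariate screen, the OPLS model (with Q2 and CV-ANOVA), the
#' volcano merge, exhaustive best-subset regression on the pre-filtered
#' top-k candidates, and hierarchical clustering of the model scores.
#'
#' @param metabolome Seeds x analytes matrix.
#' @param weights Seed weights in mg (aligned with rows).
#' @param alpha Family-wise error rate for the volcano (default 0.05).
#' @param n_ortho Orthogonal OPLS components (default 1).
#' @param folds Cross-validation folds (default 7).
#' @param cv_seed Optional fold permutation seed.
#' @param top_k Best-subset candidate count (default 20).
#' @param nvmax,nbest Best-subset search size controls.
#' @param n_clusters Clusters cut from the score dendrogram (default 3:
#'   small / medium / large seeds).
#' @return A list: `screen`, `opls` (`opls_model`), `volcano`, `subsets`,
#'   `clusters`, `summary` (R2Y, Q2, p_cv_anova, thresholds, sizes).
#' @export
metabolome_stats <- function(metabolome, weights, alpha = 0.05, n_ortho = 1,
                             folds = 7, cv_seed = NULL, top_k = 20,
                             nvmax = 5, nbest = 100, n_clusters = 3) {
  if (nrow(metabolome) != length(weights))
    stop("metabolome rows must match the number of seeds")
  screen <- univariate_screen(metabolome, weights)
  model <- opls_fit(metabolome, weights, n_ortho = n_ortho, folds = folds,
                    cv_seed = cv_seed)
  volcano <- volcano_table(screen, model$loadings, alpha = alpha)

  cand <- top_candidates(screen, k = min(top_k, sum(!screen$degenerate)))
  nvmax_eff <- min(nvmax, length(cand))
  subsets <- if (length(cand) >= 1)
    best_subset(metabolome[, cand, drop = FALSE], weights,
                nvmax = nvmax_eff, nbest = nbest) else NULL

  scores <- cbind(model$scores_pred, model$scores_ortho)
  clusters <- if (nrow(metabolome) >= n_clusters)
    cluster_scores(scores, k = n_clusters) else NULL

  list(
    screen = screen, opls = model, volcano = volcano, subsets = subsets,
    clusters = clusters,
    summary = list(
      n_seeds = nrow(metabolome), n_analytes = ncol(metabolome),
      r2y = model$r2y, q2 = model$q2, p_cv_anova = model$p_cv_anova,
      n_ortho = n_ortho, folds = folds,
      bonferroni_threshold = attr(volcano, "bonferroni_threshold"),
      n_pass_bonferroni = sum(volcano$passes_bonferroni)
    )
  )
}

#' Write a synthetic cohort to the standard file layout
#'
#' Writes `seeds.csv`, `metabolome.tsv`, `annotations.tsv` and a
#' `manifest.yaml` echoing the generator configuration together with
#' content checksums, so a run is auditable and reproducible.
#'
#' @param cohort A `seed_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "seed_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seeds_path <- file.path(dir, "seeds.csv")
  met_path <- file.path(dir, "metabolome.tsv")
  ann_path <- file.path(dir, "annotations.tsv")
  utils::write.csv(cohort$seeds, seeds_path, row.names = FALSE)
  met_df <- data.frame(seed_id = rownames(cohort$metabolome),
                       cohort$metabolome, check.names = FALSE)
  utils::write.table(met_df, met_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(cohort$annotations, ann_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  cfg$class_counts <- as.list(cfg$class_counts)
  manifest <- list(
    config = unclass(cfg),
    checksums = list(
      seeds = unname(tools::md5sum(seeds_path)),
      metabolome = unname(tools::md5sum(met_path)),
      annotations = unname(tools::md5sum(ann_path))
    )
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Write the statistics outputs of [metabolome_stats()]
#'
#' Emits `volcano.tsv`, `subsets.tsv`, `variable_scores.tsv`,
#' `scores.tsv`, `loadings.tsv` and `model_summary.json` under `dir`; all
#' tables round-trip through the standard readers.
#'
#' @param stats Output of [metabolome_stats()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_stats <- function(stats, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- base::c(
    volcano = file.path(dir, "volcano.tsv"),
    subsets = file.path(dir, "subsets.tsv"),
    variable_scores = file.path(dir, "variable_scores.tsv"),
    scores = file.path(dir, "scores.tsv"),
    loadings = file.path(dir, "loadings.tsv"),
    summary = file.path(dir, "model_summary.json")
  )
  utils::write.table(stats$volcano, paths["volcano"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(stats$subsets)) {
    utils::write.table(stats$subsets$subsets, paths["subsets"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(stats$subsets$variable_scores,
                       paths["variable_scores"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  sc <- data.frame(t_pred = stats$opls$scores_pred)
  if (!is.null(stats$opls$scores_ortho))
    sc <- cbind(sc, stats::setNames(
      as.data.frame(stats$opls$scores_ortho),
      paste0("t_ortho", seq_len(ncol(stats$opls$scores_ortho)))))
  if (!is.null(stats$clusters)) sc$cluster <- stats$clusters
  utils::write.table(sc, paths["scores"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(stats$opls$loadings, paths["loadings"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(stats$summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
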