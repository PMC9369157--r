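#' Per-mil / fraction conversion for isotope delta values
#'
#' Delta values are stored and manipulated internally as dimensionless
#' fractions (per mil / 1000), because the mass-balance equations combine
#' delta and epsilon multiplicatively, which is only dimensionally
#' consistent in fractional form. Per mil appears at I/O only.
#'
#' @param x Numeric values.
#' @return The converted values.
#' @export
permil_to_fraction <- function(x) x / 1000

#' @rdname permil_to_fraction
#' @export
fraction_to_permil <- function(x) x * 1000

#' Delta notation from isotope ratios
#'
#' `delta = R_sample / R_standard - 1`, relative to an international
#' standard (V-PDB, air N2, V-CDT, V-SMOW). Returned in per mil.
#'
#' @param r_sample,r_standard Heavy/light isotope ratios, both > 0.
#' @return Delta in per mil.
#' @examples
#' ratio_to_delta(1.01, 1)  # +10 permil
#' @export
ratio_to_delta <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be > 0")
  fraction_to_permil(r_sample / r_standard - 1)
}

#' Fractionation constants of the seed delta-2H mass balance
#'
#' Defaults: isotope fractionation in NADPH reduction `eps_a = -171` permil;
#' fractionation associated with H exchange with water `eps_h = +158`
#' permil; metabolic fractionation in synthesis `delta_cap` of 0, 80 and 70
#' permil for starch, protein and lipid; exchangeable H fractions `f` of
#' 0.33 (sugar OH groups), 0.14 (protein NH/COOH groups) and 0.75 (H
#' derived from water in triose-to-acetyl-CoA conversion and fatty-acid
#' synthesis).
#'
#' @param eps_a,eps_h Fractionation factors in per mil.
#' @param delta_cap_starch,delta_cap_protein,delta_cap_lipid Metabolic
#'   fractionations in per mil.
#' @param f_starch,f_protein,f_lipid Exchangeable H fractions in `[0, 1]`.
#' @return A `fractionation_constants` list (per-mil fields as given).
#' @export
fractionation_constants <- function(eps_a = -171, eps_h = 158,
                                    delta_cap_starch = 0,
                                    delta_cap_protein = 80,
                                    delta_cap_lipid = 70,
                                    f_starch = 0.33, f_protein = 0.14,
                                    f_lipid = 0.75) {
  f <- base::c(f_starch, f_protein, f_lipid)
  if (any(f < 0 | f > 1)) stop("exchangeable fractions f must lie in [0, 1]")
  structure(
    list(eps_a = eps_a, eps_h = eps_h,
         delta_cap_starch = delta_cap_starch,
         delta_cap_protein = delta_cap_protein,
         delta_cap_lipid = delta_cap_lipid,
         f_starch = f_starch, f_protein = f_protein, f_lipid = f_lipid),
    class = "fractionation_constants"
  )
}

#' Leaf/pod water scenarios for the delta-2H prediction
#'
#' Leaf and pod water delta-2H were not measured, so prediction runs under
#' named scenarios built from the source (rain/tap) water delta-2H of -33
#' permil: (a) moderate leaf-pod difference, leaf water enriched by +60 and
#' pod water by +30 permil over source; (b) large difference, leaf +75,
#' pod at source; (c) no leaf-pod difference, both waters at 0 permil
#' absolute. Scenario (a) is the reporting default, being closest to
#' observation. `custom` takes explicit enrichments.
#'
#' @param name One of `"a"`, `"b"`, `"c"`, `"custom"`.
#' @param source_water_delta Source water delta-2H in per mil.
#' @param leaf_enrichment,pod_enrichment Per-mil enrichments over source
#'   water (only used for `name = "custom"`).
#' @return An `isotope_scenario` list with derived absolute leaf
#'   (`delta_wl`) and pod (`delta_wp`) water delta-2H in per mil.
#' @examples
#' isotope_scenario("a")$delta_wl  # +27 permil
#' @export
isotope_scenario <- function(name = c("a", "b", "c", "custom"),
                             source_water_delta = -33,
                             leaf_enrichment = NULL, pod_enrichment = NULL) {
  name <- match.arg(name)
  if (name == "a") {
    wl <- source_water_delta + 60; wp <- source_water_delta + 30
  } else if (name == "b") {
    wl <- source_water_delta + 75; wp <- source_water_delta
  } else if (name == "c") {
    wl <- 0; wp <- 0                        # absolute, not source-relative
  } else {
    if (is.null(leaf_enrichment) || is.null(pod_enrichment))
      stop("custom scenario needs leaf_enrichment and pod_enrichment")
    wl <- source_water_delta + leaf_enrichment
    wp <- source_water_delta + pod_enrichment
  }
  structure(
    list(name = name, source_water_delta = source_water_delta,
         delta_wl = wl, delta_wp = wp),
    class = "isotope_scenario"
  )
}

#' Delta-2H of source metabolites from leaf water
#'
#' Photosynthetic source metabolites inherit leaf water delta-2H corrected
#' for the fractionation in NADPH reduction:
#' `delta_source = delta_wl * (1 + eps_a) + eps_a` (fractional form).
#'
#' @param delta_wl Leaf water delta-2H in per mil.
#' @param constants A [fractionation_constants()].
#' @return Delta-2H of source metabolites in per mil.
#' @examples
#' delta_source(0)   # -171 permil
#' delta_source(27)  # -148.617 permil
#' @export
delta_source <- function(delta_wl, constants = fractionation_constants()) {
  dwl <- permil_to_fraction(delta_wl)
  ea <- permil_to_fraction(constants$eps_a)
  fraction_to_permil(dwl * (1 + ea) + ea)
}

#' Delta-2H of a metabolite class after exchange and synthesis
#'
#' During export and use from leaves to pods, a fraction `f` of the H atoms
#' exchanges with pod water (with fractionation `eps_h`) while the rest
#' retains the source signature; synthesis subtracts a metabolic
#' fractionation `delta_cap`:
#' `delta = (1 - f) * delta_source + f * (delta_wp * (1 + eps_h) + eps_h)
#'  - delta_cap` (fractional form).
#'
#' @param d_source Source metabolite delta-2H in per mil.
#' @param delta_wp Pod water delta-2H in per mil.
#' @param f Exchangeable H fraction in `[0, 1]`.
#' @param delta_cap Metabolic fractionation in per mil.
#' @param constants A [fractionation_constants()].
#' @return Metabolite delta-2H in per mil.
#' @export
delta_metabolite <- function(d_source, delta_wp, f, delta_cap,
                             constants = fractionation_constants()) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  ds <- permil_to_fraction(d_source)
  dwp <- permil_to_fraction(delta_wp)
  eh <- permil_to_fraction(constants$eps_h)
  dc <- permil_to_fraction(delta_cap)
  fraction_to_permil((1 - f) * ds + f * (dwp * (1 + eh) + eh) - dc)
}

#' Seed bulk delta-2H as a lipid / non-lipid hydrogen mixture
#'
#' `delta_seed = (1 - x) * delta_other + x * delta_lipids`, where `x` is
#' the lipid H mole fraction and `delta_other` averages the protein and
#' starch signatures. Exactly affine in `x`.
#'
#' @param x Lipid H mole fraction in `[0, 1]`.
#' @param d_other,d_lipids Delta-2H of the non-lipid and lipid H pools, in
#'   per mil.
#' @return Seed delta-2H in per mil.
#' @export
delta_seed <- function(x, d_other, d_lipids) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  (1 - x) * d_other + x * d_lipids
}

#' Predict seed delta-2H from the lipid H mole fraction
#'
#' Composes the mass balance: source metabolites from scenario leaf water;
#' starch, protein and lipid pools by exchange/synthesis with their
#' respective `(f, delta_cap)`; the non-lipid pool as the unweighted mean
#' of protein and starch (as defined, not H-weighted; set
#' `other_weights` for a weighted variant); then the lipid mixture.
#'
#' @param x Lipid H mole fraction(s) in `[0, 1]`.
#' @param scenario An [isotope_scenario()].
#' @param constants A [fractionation_constants()].
#' @param other_weights Length-2 weights (protein, starch) for the
#'   non-lipid average; default `c(0.5, 0.5)`.
#' @return Predicted seed delta-2H in per mil (vectorised over `x`).
#' @examples
#' predict_seed_delta2h(c(0, 1), isotope_scenario("c"))
#' @export
predict_seed_delta2h <- function(x, scenario = isotope_scenario("a"),
                                 constants = fractionation_constants(),
                                 other_weights = base::c(0.5, 0.5)) {
  stopifnot(inherits(scenario, "isotope_scenario"))
  if (!isTRUE(all.equal(sum(other_weights), 1)))
    stop("other_weights must sum to 1")
  ds <- delta_source(scenario$delta_wl, constants)
  d_starch <- delta_metabolite(ds, scenario$delta_wp, constants$f_starch,
                               constants$delta_cap_starch, constants)
  d_protein <- delta_metabolite(ds, scenario$delta_wp, constants$f_protein,
                                constants$delta_cap_protein, constants)
  d_lipid <- delta_metabolite(ds, scenario$delta_wp, constants$f_lipid,
                              constants$delta_cap_lipid, constants)
  d_other <- other_weights[1] * d_protein + other_weights[2] * d_starch
  delta_seed(x, d_other, d_lipid)
}

#' Predicted delta-2H along a grid of lipid H mole fractions
#'
#' Pointwise application of [predict_seed_delta2h()], for plotting or
#' export of the scenario lines.
#'
#' @param scenario An [isotope_scenario()].
#' @param x_grid Increasing fractions in `[0, 1]` (may be empty).
#' @param constants A [fractionation_constants()].
#' @return A data.frame with columns `x` and `delta_permil`.
#' @export
scenario_line <- function(scenario, x_grid = seq(0, 1, by = 0.01),
                          constants = fractionation_constants()) {
  if (length(x_grid) == 0)
    return(data.frame(x = numeric(0), delta_permil = numeric(0)))
  if (any(x_grid < 0 | x_grid > 1)) stop("x_grid must lie in [0, 1]")
  data.frame(x = x_grid,
             delta_permil = predict_seed_delta2h(x_grid, scenario, constants))
}
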