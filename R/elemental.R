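#' Elemental composition of a seed
#'
#' Bundles the four measured elemental mass fractions of a seed (carbon,
#' nitrogen, sulphur, hydrogen) as dimensionless fractions in `[0, 1]`.
#' Oxygen and minor elements are the unmeasured remainder, so the four
#' fractions must sum to at most 1. File I/O uses percent; conversion to
#' fractions happens at the boundary (see [read_seed_table()]).
#'
#' @param c,n,s,h Mass fractions (not percent) of C, N, S and H.
#' @return An object of class `elemental_composition`: a named numeric
#'   vector with elements `c`, `n`, `s`, `h`.
#' @examples
#' elemental_composition(c = 0.45, n = 0.06, s = 0.003, h = 0.065)
#' @export
elemental_composition <- function(c, n, s, h) {
  x <- base::c(c = c, n = n, s = s, h = h)
  if (any(!is.finite(x))) stop("elemental fractions must be finite")
  if (any(x < 0)) stop("elemental fractions must be >= 0")
  if (sum(x) > 1 + 1e-9) {
    stop(sprintf("elemental fractions sum to %.4f > 1", sum(x)))
  }
  structure(x, class = "elemental_composition")
}

#' Water and mineral correction policy
#'
#' Raw elemental fractions refer to whole-seed weight, which includes
#' residual non-extractible seed water (11% by weight) and minerals (4%).
#' The biochemical mass balance applies to the organic dry matter only, so
#' observed fractions are divided by `1 - water_fraction - mineral_fraction`
#' (0.85 with the defaults).
#'
#' @param water_fraction Residual water mass fraction (default 0.11).
#' @param mineral_fraction Mineral mass fraction (default 0.04).
#' @return A `correction_policy` list with fields `water_fraction`,
#'   `mineral_fraction` and the derived `divisor`.
#' @export
correction_policy <- function(water_fraction = 0.11, mineral_fraction = 0.04) {
  if (water_fraction < 0 || mineral_fraction < 0)
    stop("correction fractions must be >= 0")
  divisor <- 1 - water_fraction - mineral_fraction
  if (divisor <= 0)
    stop("water_fraction + mineral_fraction must be < 1 (divisor <= 0)")
  structure(
    list(water_fraction = water_fraction, mineral_fraction = mineral_fraction,
         divisor = divisor),
    class = "correction_policy"
  )
}

#' Reference elemental composition of the four seed components
#'
#' Rows are the biochemical components used in the mass balance —
#' carbohydrate (starch-like), albumin (S-rich storage protein), S-poor
#' proteins plus other nitrogenous compounds (vicilins, legumins, etc.) and
#' lipid (fatty-acid-like) — and columns are their elemental weight
#' fractions in C, N, S and H. Defaults are reference compositions of
#' starch, Medicago albumin, Medicago legumins + vicilins and fatty acids.
#'
#' @param mat Optional 4 x 4 numeric matrix (components x elements)
#'   replacing the defaults; must carry the canonical dimnames.
#' @return A `component_reference` matrix with rownames
#'   `carbohydrate`, `albumin`, `s_poor_protein_other`, `lipid` and
#'   colnames `c`, `n`, `s`, `h`.
#' @examples
#' component_reference()
#' @export
component_reference <- function(mat = NULL) {
  if (is.null(mat)) {
    mat <- rbind(
      carbohydrate         = base::c(0.400, 0.000, 0.000, 0.066),
      albumin              = base::c(0.505, 0.187, 0.027, 0.069),
      s_poor_protein_other = base::c(0.519, 0.194, 0.001, 0.068),
      lipid                = base::c(0.760, 0.000, 0.000, 0.120)
    )
    colnames(mat) <- base::c("c", "n", "s", "h")
  }
  mat <- as.matrix(mat)
  if (!identical(dim(mat), base::c(4L, 4L)))
    stop("component reference must be a 4 x 4 matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("component reference must have component rownames and element colnames")
  rownames(mat) <- tolower(rownames(mat))
  colnames(mat) <- tolower(colnames(mat))
  mat <- mat[component_order(), element_order(), drop = FALSE]
  if (any(mat < 0) || any(mat > 1))
    stop("reference elemental weight fractions must lie in [0, 1]")
  if (qr(mat)$rank < 4L)
    stop("component reference matrix is rank deficient")
  structure(mat, class = base::c("component_reference", "matrix"))
}

#' Canonical component and element orderings
#'
#' Components and elements are always addressed by name; these vectors fix
#' the display/storage order used throughout the package.
#' @return Character vector of names.
#' @export
component_order <- function() {
  base::c("carbohydrate", "albumin", "s_poor_protein_other", "lipid")
}

#' @rdname component_order
#' @export
element_order <- function() base::c("c", "n", "s", "h")

#' Read a component reference matrix from CSV
#'
#' Expects columns `component`, `C`, `N`, `S`, `H` (case-insensitive). The
#' packaged default is in `system.file("extdata", "component_reference.csv",
#' package = "seedallometry")`.
#'
#' @param path CSV file path.
#' @return A [component_reference()] matrix.
#' @export
read_component_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(base::c("component", element_order()) %in% names(df)))
    stop("reference CSV needs columns component, C, N, S, H")
  mat <- as.matrix(df[, element_order()])
  rownames(mat) <- df$component
  component_reference(mat)
}

#' Correct elemental fractions for residual water and minerals
#'
#' Divides each measured fraction by the policy divisor (default 0.85) so
#' that fractions refer to the organic dry matter entering the mass
#' balance. The operation is linear in the input.
#'
#' @param raw An [elemental_composition()].
#' @param policy A [correction_policy()].
#' @param seed_id Optional identifier used in error messages.
#' @return The corrected `elemental_composition`.
#' @examples
#' correct_composition(elemental_composition(0.3825, 0, 0, 0))
#' @export
correct_composition <- function(raw, policy = correction_policy(),
                                seed_id = NULL) {
  stopifnot(inherits(policy, "correction_policy"))
  x <- unclass(raw) / policy$divisor
  if (sum(x) > 1 + 1e-9) {
    who <- if (is.null(seed_id)) "input" else paste0("seed '", seed_id, "'")
    stop(sprintf(
      "corrected elemental fractions of %s sum to %.4f > 1: inconsistent data",
      who, sum(x)))
  }
  elemental_composition(x[["c"]], x[["n"]], x[["s"]], x[["h"]])
}

#' Biochemical composition of a seed
#'
#' The four component mass fractions recovered by the mass balance, the
#' per-element absolute fitting residual, and their total. The total is
#' reported, not forced to one; a warning is emitted when it falls outside
#' `[0.90, 1.10]`, which usually indicates inconsistent elemental data.
#'
#' @param w_carb,w_alb,w_spp,w_lip Component mass fractions.
#' @param residual Named numeric of per-element absolute residuals
#'   (defaults to zeros).
#' @return A `biochemical_composition` list with fields `fractions`
#'   (named vector in [component_order()]), `residual` and `total`.
#' @export
biochemical_composition <- function(w_carb, w_alb, w_spp, w_lip,
                                    residual = NULL) {
  w <- base::c(carbohydrate = w_carb, albumin = w_alb,
               s_poor_protein_other = w_spp, lipid = w_lip)
  if (any(!is.finite(w)) || any(w < -1e-12))
    stop("component fractions must be finite and >= 0")
  w <- pmax(w, 0)
  if (is.null(residual)) residual <- stats::setNames(rep(0, 4), element_order())
  if (any(residual < 0)) stop("residuals must be >= 0")
  structure(
    list(fractions = w, residual = residual, total = sum(w)),
    class = "biochemical_composition"
  )
}

#' Forward linear mixing model: components to elements
#'
#' Each elemental fraction is the component-fraction-weighted sum of the
#' reference elemental weight fractions. This is the model whose squared
#' misfit [invert_composition()] minimises; it is exposed so that the
#' synthetic generator can produce elemental data with an exactly known
#' biochemical truth, and for round-trip testing.
#'
#' @param biochem A [biochemical_composition()] (residuals ignored).
#' @param ref A [component_reference()] matrix.
#' @return An [elemental_composition()].
#' @examples
#' forward_composition(biochemical_composition(0.37, 0.13, 0.35, 0.15))
#' @export
forward_composition <- function(biochem, ref = component_reference()) {
  w <- biochem$fractions[component_order()]
  e <- as.vector(w %*% ref)
  names(e) <- element_order()
  elemental_composition(e[["c"]], e[["n"]], e[["s"]], e[["h"]])
}

#' Invert corrected elemental fractions into biochemical composition
#'
#' Solves the 4-equation mass balance for the four component fractions by
#' nonnegative least squares (Lawson--Hanson active set via
#' [pracma::lsqnonneg()]): minimise the sum of squared differences between
#' modelled and observed corrected composition subject to fractions >= 0.
#' No sum-to-one constraint is imposed; the total is reported and a warning
#' raised if it leaves `[0.90, 1.10]`. The solve is deterministic.
#'
#' @param corrected A corrected [elemental_composition()].
#' @param ref A [component_reference()] matrix.
#' @param total_warn_range Warn when the fraction total leaves this range.
#' @return A [biochemical_composition()] with per-element absolute
#'   residuals `|modelled - observed|`.
#' @examples
#' e <- forward_composition(biochemical_composition(0.37, 0.13, 0.35, 0.15))
#' invert_composition(e)$fractions
#' @export
invert_composition <- function(corrected, ref = component_reference(),
                               total_warn_range = base::c(0.90, 1.10)) {
  M <- t(unclass(ref))                     # elements x components
  e <- unclass(corrected)[element_order()]
  if (all(e == 0)) {
    return(biochemical_composition(0, 0, 0, 0))
  }
  fit <- pracma::lsqnonneg(M, as.vector(e))
  w <- fit$x
  resid <- abs(as.vector(M %*% w) - e)
  names(resid) <- element_order()
  out <- biochemical_composition(w[1], w[2], w[3], w[4], residual = resid)
  if (out$total < total_warn_range[1] || out$total > total_warn_range[2]) {
    warning(sprintf(
      "component fractions total %.3f outside [%.2f, %.2f]; elemental data may be inconsistent",
      out$total, total_warn_range[1], total_warn_range[2]))
  }
  out
}

#' Lipid hydrogen mole fraction
#'
#' The share of a seed's hydrogen atoms contributed by its lipid component:
#' `x = w_lip * H_lip / sum_i(w_i * H_i)` over the reference H column.
#' Because every H atom has the same mass, H weight shares equal H mole
#' shares. This is the mixing coordinate of the seed delta-2H model.
#'
#' @param biochem A [biochemical_composition()].
#' @param ref A [component_reference()] matrix.
#' @return A fraction in `[0, 1]`.
#' @examples
#' lipid_h_mole_fraction(biochemical_composition(0.37, 0.13, 0.35, 0.15))
#' @export
lipid_h_mole_fraction <- function(biochem, ref = component_reference()) {
  w <- biochem$fractions[component_order()]
  if (all(w == 0)) stop("all component fractions are zero: x is undefined")
  hcol <- unclass(ref)[, "h"]
  denom <- sum(w * hcol)
  unname(w[["lipid"]] * hcol[["lipid"]] / denom)
}
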