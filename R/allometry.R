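#' Ordinary least squares regression of one response on one predictor
#'
#' Wraps [stats::lm()] and returns the quantities the allometry screen
#' needs: slope (response units per mg when the predictor is seed weight),
#' intercept, R2, two-sided p-value of the slope (F-test, equivalent to
#' the t-test for a single predictor) and n.
#'
#' @param x Predictor vector.
#' @param y Response vector (same length).
#' @return A one-row data.frame: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, plus 95% CI bounds `slope_lo`, `slope_hi`.
#' @examples
#' fit_linear(1:10, 2 * (1:10) + 1)
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("degenerate input: predictor has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit, "x", level = 0.95)
  p <- if (nrow(co) < 2 || !is.finite(co["x", 4])) 1 else co["x", 4]
  data.frame(
    slope = unname(stats::coef(fit)[["x"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = sm$r.squared,
    p_value = p,
    n = n,
    slope_lo = unname(ci[1, 1]),
    slope_hi = unname(ci[1, 2])
  )
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`: with `alpha = 0.05` over a 244-analyte metabolome this is
#' 2.049e-4, the family-wise threshold drawn on the volcano.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests, >= 1.
#' @return The per-test p-value threshold.
#' @examples
#' bonferroni_threshold(0.05, 244)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Per-analyte linear regression screen against seed weight
#'
#' Runs [fit_linear()] of every analyte column on the weights, preserving
#' column order. Constant (zero-variance) columns are flagged degenerate
#' with a warning, carry NA statistics, and are excluded downstream.
#'
#' @param matrix Seeds x analytes intensity matrix with column names; rows
#'   must align with `weights`.
#' @param weights Seed weights in mg.
#' @return A data.frame with one row per analyte: `analyte`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `degenerate`.
#' @export
univariate_screen <- function(matrix, weights) {
  if (nrow(matrix) != length(weights))
    stop("matrix rows must match the number of weights")
  if (is.null(colnames(matrix))) stop("matrix must have analyte column names")
  res <- lapply(seq_len(ncol(matrix)), function(j) {
    yj <- matrix[, j]
    if (stats::var(yj) == 0) {
      data.frame(analyte = colnames(matrix)[j], slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 p_value = NA_real_, n = length(yj), degenerate = TRUE)
    } else {
      f <- fit_linear(weights, yj)
      data.frame(analyte = colnames(matrix)[j], slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 p_value = f$p_value, n = f$n, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  ndeg <- sum(out$degenerate)
  if (ndeg > 0)
    warning(sprintf("%d constant analyte column(s) flagged degenerate", ndeg))
  rownames(out) <- NULL
  out
}

#' Volcano table: univariate significance against the OPLS loading
#'
#' Merges the univariate screen with the predictive OPLS loading per
#' analyte. The best biomarkers of seed weight carry both a large
#' `-log10(p)` and a large absolute loading. `passes_bonferroni` uses a
#' strict inequality at `alpha / m`; degenerate analytes are dropped.
#'
#' @param screen Output of [univariate_screen()].
#' @param loadings Named numeric vector (or data.frame with `analyte` and
#'   `loading_pq1`) of predictive loadings covering every screened analyte.
#' @param alpha Family-wise error rate.
#' @param m Number of tests; defaults to the number of non-degenerate
#'   analytes.
#' @return A data.frame sorted by `neg_log10_p` descending: `analyte`,
#'   `loading_pq1`, `neg_log10_p`, `p_value`, `passes_bonferroni`.
#' @export
volcano_table <- function(screen, loadings, alpha = 0.05, m = NULL) {
  if (is.data.frame(loadings)) {
    loadings <- stats::setNames(loadings$loading_pq1, loadings$analyte)
  }
  keep <- screen[!screen$degenerate, , drop = FALSE]
  missing <- setdiff(keep$analyte, names(loadings))
  if (length(missing) > 0)
    stop("no loading for analyte(s): ", paste(missing, collapse = ", "))
  if (is.null(m)) m <- nrow(keep)
  thr <- bonferroni_threshold(alpha, m)
  out <- data.frame(
    analyte = keep$analyte,
    loading_pq1 = unname(loadings[keep$analyte]),
    neg_log10_p = -log10(keep$p_value),
    p_value = keep$p_value,
    passes_bonferroni = keep$p_value < thr
  )
  out <- out[order(-out$neg_log10_p), ]
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Keep the strongest univariate correlates as best-subset candidates
#'
#' Exhaustive subset search is infeasible over a whole metabolome, so the
#' candidate set is restricted to the top-k analytes by univariate R2
#' before enumeration.
#'
#' @param screen Output of [univariate_screen()].
#' @param k Number of analytes to keep (default 20).
#' @return Character vector of analyte names, strongest first.
#' @export
top_candidates <- function(screen, k = 20) {
  keep <- screen[!screen$degenerate, , drop = FALSE]
  keep <- keep[order(-keep$r_squared), , drop = FALSE]
  utils::head(keep$analyte, k)
}

#' Exhaustive best-subset linear regression
#'
#' Enumerates every predictor subset of size 1..`nvmax` and retains the
#' `nbest` highest-R2 models per size (multiple linear regression with
#' variable elimination). Also reports, per variable, the best R2 of any
#' retained model containing it — the ordinate of the correlogram of best
#' weight correlates. Refuses more than 25 candidate predictors; use
#' [top_candidates()] first. Ties are broken deterministically by
#' enumeration (column) order.
#'
#' @param x Predictor matrix with column names (seeds x candidates).
#' @param y Response vector (seed weight).
#' @param nvmax Maximum subset size (default 5).
#' @param nbest Models retained per size (default 100).
#' @return A list with `subsets` (data.frame: `size`, `rank`, `r_squared`,
#'   `variables` as a comma-joined string) and `variable_scores`
#'   (data.frame: `variable`, `best_r_squared`).
#' @export
best_subset <- function(x, y, nvmax = 5, nbest = 100) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(colnames(x))) stop("x must have column names")
  if (p > 25)
    stop("refusing exhaustive search over > 25 predictors; pre-filter candidates")
  if (nvmax > p) stop("nvmax exceeds the number of predictors")
  n <- length(y)
  if (nrow(x) != n) stop("x rows must match length(y)")

  # R2 via the Gram matrix: for subset S, R2 = b' G[S,S]^{-1} b / Syy with
  # b = X_S'y and everything centred.
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(xc)
  b <- as.vector(crossprod(xc, yc))
  syy <- sum(yc^2)
  if (syy == 0) stop("response has zero variance")

  subset_r2 <- function(idx) {
    Gs <- G[idx, idx, drop = FALSE]
    bs <- b[idx]
    sol <- tryCatch(solve(Gs, bs), error = function(e) {
      # exactly singular (duplicate columns): minimum-norm solution keeps
      # the enumeration deterministic
      as.vector(MASS::ginv(Gs) %*% bs)
    })
    max(0, min(1, sum(bs * sol) / syy))
  }

  rows <- list()
  for (size in seq_len(nvmax)) {
    combos <- utils::combn(p, size)
    r2 <- apply(combos, 2, subset_r2)
    ord <- order(-r2, seq_along(r2))       # deterministic tie-break
    keep <- utils::head(ord, nbest)
    rows[[size]] <- data.frame(
      size = size,
      rank = seq_along(keep),
      r_squared = r2[keep],
      variables = apply(combos[, keep, drop = FALSE], 2, function(ix)
        paste(colnames(x)[ix], collapse = ","))
    )
  }
  subsets <- do.call(rbind, rows)
  rownames(subsets) <- NULL

  var_best <- vapply(colnames(x), function(v) {
    hit <- vapply(strsplit(subsets$variables, ","), function(vs) v %in% vs,
                  logical(1))
    if (any(hit)) max(subsets$r_squared[hit]) else NA_real_
  }, numeric(1))
  list(
    subsets = subsets,
    variable_scores = data.frame(variable = colnames(x),
                                 best_r_squared = unname(var_best))
  )
}
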