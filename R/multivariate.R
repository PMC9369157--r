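#' Unit-variance scaling model
#'
#' Centres every column and scales it to unit variance (the preprocessing
#' convention for X in latent-variable metabolomics models; y is centred
#' only). Constant columns are dropped with a warning. The model stores
#' the per-column centre/scale so new data can be projected and scaled
#' data inverted exactly.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return A list of class `uv_scaling`: `x` (scaled matrix), `center`,
#'   `scale`, `kept` (column names retained).
#' @export
uv_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to scale")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sprintf("dropping %d constant column(s): %s", sum(!keep),
                    paste(colnames(x)[!keep], collapse = ", ")))
  x <- x[, keep, drop = FALSE]
  ctr <- colMeans(x)
  scl <- sds[keep]
  structure(
    list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"),
         center = ctr, scale = scl, kept = colnames(x)),
    class = "uv_scaling"
  )
}

#' Apply / invert a unit-variance scaling model
#'
#' @param model A [uv_scale()] model.
#' @param x_new New data with (at least) the model's kept columns.
#' @return The scaled (or unscaled) matrix.
#' @export
uv_apply <- function(model, x_new) {
  x_new <- as.matrix(x_new)
  missing <- setdiff(model$kept, colnames(x_new))
  if (length(missing) > 0)
    stop("new data lacks column(s): ", paste(missing, collapse = ", "))
  x_new <- x_new[, model$kept, drop = FALSE]
  sweep(sweep(x_new, 2, model$center), 2, model$scale, "/")
}

#' @rdname uv_apply
#' @param x_scaled A matrix on the scaled scale.
#' @export
uv_invert <- function(model, x_scaled) {
  sweep(sweep(as.matrix(x_scaled), 2, model$scale, "*"), 2, model$center, "+")
}

#' Principal component analysis with Hotelling T2 screening
#'
#' PCA by singular value decomposition on unit-variance-scaled data, with
#' the per-sample Hotelling T2 statistic over the first `k` components.
#' Samples outside the confidence region at the chosen level (99% for
#' outlier exclusion by convention here, 95% for display ellipses) are
#' candidate outliers.
#'
#' @param x Samples x variables matrix.
#' @param k Number of components, `k <= min(n - 1, p)`.
#' @param scale Unit-variance scale the columns first (default TRUE).
#' @return A list of class `pca_model`: `scores`, `loadings`,
#'   `explained_variance` (proportions), `t2` (per sample), `n`, `k`.
#' @export
pca_fit <- function(x, k = 2, scale = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > min(n - 1, ncol(x))) stop("k exceeds min(n - 1, p)")
  sc <- if (scale) uv_scale(x) else NULL
  xs <- if (scale) sc$x else sweep(x, 2, colMeans(x))
  sv <- svd(xs)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  lambda <- sv$d^2 / (n - 1)
  t2 <- rowSums(sweep(scores[, seq_len(k), drop = FALSE]^2, 2,
                      lambda[seq_len(k)], "/"))
  structure(
    list(scores = scores[, seq_len(k), drop = FALSE],
         loadings = sv$v[, seq_len(k), drop = FALSE],
         explained_variance = lambda / sum(lambda),
         lambda = lambda[seq_len(k)], t2 = t2, n = n, k = k,
         scaling = sc),
    class = "pca_model"
  )
}

#' @rdname pca_fit
#' @param model A `pca_model`.
#' @param level Confidence level of the Hotelling region (default 0.99).
#' @return For `hotelling_outliers`: logical vector flagging samples whose
#'   T2 exceeds the F-based critical value.
#' @export
hotelling_outliers <- function(model, level = 0.99) {
  n <- model$n; k <- model$k
  crit <- k * (n - 1) * (n + 1) / (n * (n - k)) *
    stats::qf(level, k, n - k)
  model$t2 > crit
}

# Single-component PLS-1 / OPLS predictive step on centred-scaled data.
# Returns weights w (unit norm), scores t, X-loading p, y-loading q.
pls1_component <- function(xs, yc) {
  w <- as.vector(crossprod(xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("y is orthogonal to every column of X; no predictive direction")
  w <- w / nw
  t <- as.vector(xs %*% w)
  tt <- sum(t^2)
  if (tt == 0) stop("degenerate predictive score (all zero)")
  p <- as.vector(crossprod(xs, t)) / tt
  q <- sum(yc * t) / tt
  list(w = w, t = t, p = p, q = q)
}

# OPLS-1 core on already centred/scaled xs and centred yc: strips n_ortho
# y-orthogonal components, then fits one predictive PLS component.
opls_core <- function(xs, yc, n_ortho) {
  p_names <- colnames(xs)
  W_o <- P_o <- NULL
  T_o <- NULL
  for (a in seq_len(n_ortho)) {
    w <- as.vector(crossprod(xs, yc))
    w <- w / sqrt(sum(w^2))
    t <- as.vector(xs %*% w)
    p <- as.vector(crossprod(xs, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break                  # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- as.vector(xs %*% w_o)
    p_o <- as.vector(crossprod(xs, t_o)) / sum(t_o^2)
    xs <- xs - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  comp <- pls1_component(xs, yc)
  fitted <- comp$t * comp$q
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  list(w = stats::setNames(comp$w, p_names), t = comp$t,
       p = stats::setNames(comp$p, p_names), q = comp$q,
       W_o = W_o, P_o = P_o, T_o = T_o,
       fitted_centred = fitted, r2y = r2y)
}

#' Fit an OPLS regression model with a continuous response
#'
#' Orthogonal projections to latent structures for a single continuous y
#' (here seed weight): `n_ortho` components of y-orthogonal X-variation
#' are removed NIPALS-style, then one predictive PLS component is fitted.
#' The predictive X-loading (`pq1`) per analyte is what the volcano plot
#' uses. With `n_ortho = 0` the model is exactly single-component PLS-1.
#' R2Y is computed from the fitted values; Q2 by [q2_cross_validation()]
#' (total-PRESS definition) and the model p-value by [cv_anova()], both on
#' the same fold assignment.
#'
#' @param x Samples x analytes matrix (raw; scaling handled internally).
#' @param y Response vector.
#' @param n_ortho Number of orthogonal components (default 1).
#' @param folds Cross-validation folds for Q2 / CV-ANOVA (default 7);
#'   `folds = 0` skips validation.
#' @param cv_seed Optional integer making the fold permutation
#'   reproducible; `NULL` uses deterministic interleaved folds.
#' @param scale Unit-variance scale X (default TRUE); y is always centred.
#' @return An object of class `opls_model`: scores and loadings of the
#'   predictive and orthogonal components, `r2y`, `q2`, `p_cv_anova`,
#'   `loadings` (data.frame `analyte`, `loading_pq1`), fitted values, and
#'   the scaling model.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("a", 1:10)))
#' y <- x[, 1] + rnorm(20, 0, 0.1)
#' m <- opls_fit(x, y)
#' c(m$r2y, m$q2)
#' @export
opls_fit <- function(x, y, n_ortho = 1, folds = 7, cv_seed = NULL,
                     scale = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) != length(y)) stop("x rows must match length(y)")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  sc <- if (scale) uv_scale(x) else NULL
  x_center <- if (scale) NULL else colMeans(x)
  xs <- if (scale) sc$x else sweep(x, 2, x_center)
  if (is.null(colnames(xs))) colnames(xs) <- paste0("V", seq_len(ncol(xs)))
  y_mean <- mean(y)
  yc <- y - y_mean
  if (sum(yc^2) == 0) stop("response has zero variance")
  core <- opls_core(xs, yc, n_ortho)
  fitted <- core$fitted_centred + y_mean

  q2 <- NA_real_; p_cv <- NA_real_; cv <- NULL
  if (folds >= 2) {
    cv <- q2_cross_validation(x, y, folds = folds, n_ortho = n_ortho,
                              cv_seed = cv_seed, scale = scale)
    q2 <- cv$q2
    p_cv <- cv_anova(cv)$p_value
  }
  structure(
    list(weights = core$w, scores_pred = core$t, loading_p = core$p,
         loading_q = core$q,
         ortho_weights = core$W_o, ortho_loadings = core$P_o,
         scores_ortho = core$T_o,
         r2y = core$r2y, q2 = q2, p_cv_anova = p_cv,
         fitted = fitted, y_mean = y_mean, n_ortho = n_ortho,
         scaling = sc, scale = scale, x_center = x_center,
         loadings = data.frame(analyte = names(core$p),
                               loading_pq1 = unname(core$p)),
         cv = cv),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS model: 1 predictive + %d orthogonal component(s)\n", x$n_ortho))
  cat(sprintf("  R2Y = %.3f", x$r2y))
  if (!is.na(x$q2)) cat(sprintf(", Q2 = %.3f (%d-fold)", x$q2, x$cv$folds))
  if (!is.na(x$p_cv_anova)) cat(sprintf(", P_CV-ANOVA = %.3g", x$p_cv_anova))
  cat("\n")
  invisible(x)
}

#' Predict the response for new samples from an OPLS model
#'
#' New data are projected with the training scaling, the stored orthogonal
#' components are stripped, and the predictive component score is mapped
#' back to the original y scale.
#'
#' @param object An `opls_model`.
#' @param x_new Matrix whose columns match the training columns.
#' @param ... Unused.
#' @return Predicted y values.
#' @export
predict.opls_model <- function(object, x_new, ...) {
  x_new <- as.matrix(x_new)
  if (object$scale) {
    xs <- uv_apply(object$scaling, x_new)
  } else {
    if (!is.null(colnames(x_new))) {
      missing <- setdiff(names(object$weights), colnames(x_new))
      if (length(missing) > 0)
        stop("new data lacks column(s): ", paste(missing, collapse = ", "))
      x_new <- x_new[, names(object$weights), drop = FALSE]
    }
    xs <- sweep(x_new, 2, object$x_center)
  }
  if (!is.null(object$ortho_weights)) {
    for (a in seq_len(ncol(object$ortho_weights))) {
      t_o <- as.vector(xs %*% object$ortho_weights[, a])
      xs <- xs - tcrossprod(t_o, object$ortho_loadings[, a])
    }
  }
  t_new <- as.vector(xs %*% object$weights)
  t_new * object$loading_q + object$y_mean
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic cross-validation fold assignment
#'
#' With `cv_seed = NULL`, folds are assigned by interleaving sample order
#' (fully deterministic); with an integer seed, a reproducible random
#' permutation is used. Errors if any fold would hold fewer than 2
#' samples, guarding Q2 against near-empty test folds.
#'
#' @param n Number of samples.
#' @param folds Number of folds, >= 2.
#' @param cv_seed Optional integer seed.
#' @return Integer fold label per sample.
#' @export
fold_assignment <- function(n, folds, cv_seed = NULL) {
  if (folds < 2) stop("need at least 2 folds")
  if (n < 2 * folds) stop("a fold would hold fewer than 2 samples")
  f <- rep_len(seq_len(folds), n)
  if (!is.null(cv_seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(cv_seed)
    f <- sample(f)
  }
  f
}

#' Cross-validated Q2 of an OPLS model
#'
#' Q2 = 1 - PRESS / TSS with total PRESS pooled over folds and TSS taken
#' about the overall mean. Scaling and the model are re-estimated inside
#' every training fold. Also returns the cross-validated predictions and
#' the fold-mean (null model) PRESS used by [cv_anova()].
#'
#' @param x,y Training data.
#' @param folds Number of folds (default 7).
#' @param n_ortho Orthogonal components (default 1).
#' @param cv_seed Optional fold permutation seed (see [fold_assignment()]).
#' @param scale Unit-variance scale X inside each fold.
#' @return A list of class `opls_cv`: `q2`, `press`, `press0`, `tss`,
#'   `y_cv` (out-of-fold predictions), `fold`, `folds`, `n_components`.
#' @export
q2_cross_validation <- function(x, y, folds = 7, n_ortho = 1, cv_seed = NULL,
                                scale = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- length(y)
  fold <- fold_assignment(n, folds, cv_seed)
  y_cv <- y0_cv <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    test <- fold == k
    m <- opls_fit(x[!test, , drop = FALSE], y[!test], n_ortho = n_ortho,
                  folds = 0, scale = scale)
    y_cv[test] <- predict(m, x[test, , drop = FALSE])
    y0_cv[test] <- mean(y[!test])
  }
  tss <- sum((y - mean(y))^2)
  press <- sum((y - y_cv)^2)
  press0 <- sum((y - y0_cv)^2)
  structure(
    list(q2 = 1 - press / tss, press = press, press0 = press0, tss = tss,
         y_cv = y_cv, fold = fold, folds = folds,
         n_components = 1 + n_ortho),
    class = "opls_cv"
  )
}

#' CV-ANOVA significance of an OPLS model
#'
#' F-type comparison of the cross-validated predictive residuals against a
#' null, mean-only model cross-validated on the same folds:
#' `F = ((PRESS0 - PRESS) / df1) / (PRESS / df2)` with `df1` the number of
#' fitted latent components and `df2 = n - df1 - 1` (residual-count-based
#' degrees of freedom). `p = P(F(df1, df2) >= F)`, capped at 1 when the
#' model does not beat the null. The test is conservative under the null:
#' cross-validation already penalises model complexity, so PRESS rarely
#' beats PRESS0 by chance and null p-values pile up near 1 rather than
#' being uniform.
#'
#' @param cv An `opls_cv` object from [q2_cross_validation()].
#' @return A list: `p_value`, `f_statistic`, `df1`, `df2`, `press`,
#'   `press0`.
#' @export
cv_anova <- function(cv) {
  stopifnot(inherits(cv, "opls_cv"))
  n <- length(cv$y_cv)
  df1 <- cv$n_components
  df2 <- n - df1 - 1
  if (df2 < 1) stop("too few samples for CV-ANOVA degrees of freedom")
  if (cv$press0 <= 0) {
    warning("degenerate null residuals; returning p = 1")
    return(list(p_value = 1, f_statistic = NA_real_, df1 = df1, df2 = df2,
                press = cv$press, press0 = cv$press0))
  }
  f <- ((cv$press0 - cv$press) / df1) / (cv$press / df2)
  p <- if (!is.finite(f)) 0 else if (f <= 0) 1 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  list(p_value = p, f_statistic = f, df1 = df1, df2 = df2,
       press = cv$press, press0 = cv$press0)
}

#' Hierarchical clustering of model scores
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of the
#' sample scores of a latent-variable model; used to check that score
#' space organises seeds by weight.
#'
#' @param scores Samples x components score matrix (or vector).
#' @param k Number of clusters to cut.
#' @return Integer cluster label per sample.
#' @export
cluster_scores <- function(scores, k = 2) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 samples")
  if (k > nrow(scores)) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  stats::cutree(hc, k = k)
}
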