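# Independent oracles used across the suite. These are written from the
# defining formulas, deliberately sharing no code with the package paths
# they check.

# Single-component PLS-1 fitted values, direct formulas on centred data:
# w = X'y (normalised), t = Xw, q = t'y / t't, yhat = t q + mean(y).
oracle_pls1_fitted <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  w <- drop(t(xc) %*% yc)
  w <- w / sqrt(sum(w^2))
  t <- drop(xc %*% w)
  q <- sum(t * yc) / sum(t * t)
  t * q + mean(y)
}

# OLS slope/intercept/R2 from the closed-form normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Random nonnegative component-fraction vectors with total <= `max_total`.
random_fraction_vectors <- function(n, max_total = 1.1) {
  t(replicate(n, {
    v <- stats::runif(4, 0, 1)
    v * stats::runif(1, 0, max_total) / sum(v)
  }))
}
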