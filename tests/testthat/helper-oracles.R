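# Brute-force threshold oracle: minimize fdp_hat over a dense t-grid that
# also contains every statistic magnitude, then select {s >= t}.
brute_force_threshold <- function(stats, q, offset = 0, grid_n = 1000) {
  hi <- max(abs(stats))
  if (hi == 0) return(list(threshold = Inf, selected = integer(0)))
  grid <- sort(unique(c(seq(hi / grid_n, hi, length.out = grid_n),
                        abs(stats[stats != 0]))))
  fdp <- vapply(grid, function(t) fdp_hat(stats, t, offset), numeric(1))
  ok <- which(fdp <= q)
  if (!length(ok)) return(list(threshold = Inf, selected = integer(0)))
  tq <- grid[ok[1]]
  list(threshold = tq, selected = which(stats >= tq))
}

# Analytic OLS coefficient covariance (up to sigma^2) of a design.
coef_cov_unscaled <- function(D) solve(crossprod(D))

# Quick iid-Gaussian regression dataset for method-level tests.
tiny_dataset <- function(n, p, k, seed, beta_value = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  support <- sort(sample.int(p, k))
  beta <- numeric(p)
  beta[support] <- if (is.null(beta_value)) {
    rnorm(k, 0, sqrt(0.15 * 60 / max(k, 1)))
  } else beta_value
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta, support = support)
}
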