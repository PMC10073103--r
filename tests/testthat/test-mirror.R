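test_that("mirror pair construction identities hold", {
  set.seed(1)
  X <- matrix(rnorm(30 * 5), 30, 5)
  z <- rnorm(30)
  D <- make_mirror_pair(X, 3, 1.7, z)
  expect_equal(dim(D), c(30, 6))
  expect_equal((D[, 3] + D[, 4]) / 2, X[, 3])        # average recovers x_j
  expect_equal((D[, 3] - D[, 4]) / (2 * 1.7), z)     # difference recovers z
  expect_equal(D[, c(1, 2, 5, 6)], X[, c(1, 2, 4, 5)])
  # degenerate diagnostic: c = 0 collapses the pair
  D0 <- make_mirror_pair(X, 3, 0, z)
  expect_equal(D0[, 3], D0[, 4])
  expect_error(make_mirror_pair(X, 3, -1, z), "nonnegative")
  expect_error(make_mirror_pair(X, 9, 1, z), "range")
})

test_that("OLS mirror scalar has its closed form in special cases", {
  set.seed(2)
  # single column: no projection, c = ||x|| / ||z||
  x <- matrix(rnorm(40), 40, 1)
  z <- rnorm(40)
  expect_equal(mirror_scalar_ols(x, 1, z),
               sqrt(sum(x^2)) / sqrt(sum(z^2)))
  # x_j orthogonal to the other columns and to z, with ||x_j|| = 2 ||z||
  Q <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6)))
  X <- cbind(Q[, 1:3], Q[, 4] * 6)
  z <- Q[, 5] * 3
  expect_equal(mirror_scalar_ols(X, 4, z), 2)
})

test_that("at the OLS scalar the mirror pair coefficients are uncorrelated
           and sum/difference have equal variance", {
  set.seed(3)
  for (i in 1:5) {
    X <- matrix(rnorm(50 * 5), 50, 5)
    z <- rnorm(50)
    j <- sample(5, 1)
    cj <- mirror_scalar_ols(X, j, z)
    D <- make_mirror_pair(X, j, cj, z)
    V <- coef_cov_unscaled(D)
    ip <- j; im <- j + 1
    scale_ref <- sqrt(V[ip, ip] * V[im, im])
    expect_lt(abs(V[ip, im]) / scale_ref, 1e-10)       # cov(b+, b-) = 0
    var_sum <- V[ip, ip] + V[im, im] + 2 * V[ip, im]
    var_diff <- V[ip, ip] + V[im, im] - 2 * V[ip, im]
    expect_equal(var_sum, var_diff, tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the offending columns", {
  set.seed(4)
  X <- matrix(rnorm(20 * 4), 20, 4)
  X <- cbind(X, X[, 1] + X[, 2])
  expect_error(mirror_scalar_ols(X, 3, rnorm(20)), "rank deficient")
})

test_that("the fast OLS path reproduces the direct mirror-design fit", {
  set.seed(5)
  n <- 60; p <- 7
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(2, -1, rep(0, p - 2))
  y <- drop(X %*% beta) + rnorm(n)
  seed <- 31
  gm <- gm_statistics(X, y, standardize = FALSE, seed = seed)
  # replay the same perturbation stream against naive per-j lm fits
  set.seed(seed)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  for (j in seq_len(p)) {
    z <- rnorm(n)
    z <- z - mean(z)
    cj <- mirror_scalar_ols(Xc, j, z)
    D <- make_mirror_pair(Xc, j, cj, z)
    fit <- lm.fit(D, yc)
    expect_equal(gm$c[j], cj, tolerance = 1e-9)
    expect_equal(gm$beta_plus[j], unname(fit$coefficients[j]),
                 tolerance = 1e-8)
    expect_equal(gm$beta_minus[j], unname(fit$coefficients[j + 1]),
                 tolerance = 1e-8)
  }
  expect_equal(gm$M, abs(gm$beta_plus + gm$beta_minus) -
                 abs(gm$beta_plus - gm$beta_minus))
})

test_that("high-dimensional scalar reduces to the OLS formula", {
  set.seed(6)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  z <- rnorm(n)
  # empty active set: no projection at all
  expect_equal(mirror_scalar_highdim(X, 2, z, integer(0)),
               sqrt(sum(X[, 2]^2)) / sqrt(sum(z^2)))
  # full active set: identical to the OLS projection
  expect_equal(mirror_scalar_highdim(X, 2, z, 1:p, rep(1, p)),
               mirror_scalar_ols(X, 2, z))
  # oversized active set is truncated with a warning
  n2 <- 8
  X2 <- matrix(rnorm(n2 * 12), n2, 12)
  expect_warning(
    mirror_scalar_highdim(X2, 1, rnorm(n2), 2:12, seq(0.1, 1.1, by = 0.1)),
    "truncated")
})

test_that("a dominant causal variable gets the largest, positive statistic", {
  d <- tiny_dataset(200, 50, 1, seed = 9, beta_value = 10)
  gm <- gm_statistics(d$X, d$y, seed = 10)
  expect_equal(which.max(gm$M), d$support)
  expect_gt(gm$M[d$support], 0)
  expect_true(all(gm$c > 0))
})

test_that("mirror statistics are reproducible and sign-balanced under the
           global null", {
  d <- tiny_dataset(120, 40, 0, seed = 12)
  a <- gm_statistics(d$X, d$y, seed = 3)
  b <- gm_statistics(d$X, d$y, seed = 3)
  expect_identical(a$M, b$M)
  # pooled sign balance over replicated nulls
  signs <- unlist(lapply(1:10, function(r) {
    d <- tiny_dataset(100, 30, 0, seed = 100 + r)
    sign(gm_statistics(d$X, d$y, seed = 200 + r)$M)
  }))
  npos <- sum(signs > 0); ntot <- sum(signs != 0)
  expect_gt(stats::binom.test(npos, ntot)$p.value, 0.001)
})

test_that("lasso-regime mirror statistics work when p exceeds n", {
  set.seed(14)
  n <- 60; p <- 80
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p); beta[5] <- 8
  y <- drop(X %*% beta) + rnorm(n)
  gm <- gm_statistics(X, y, seed = 15)
  expect_equal(gm$regime, "l1")
  expect_length(gm$M, p)
  expect_true(all(is.finite(gm$M)))
  expect_equal(which.max(gm$M), 5L)
  expect_gt(gm$M[5], 0)
})

test_that("non-finite inputs are rejected before fitting", {
  X <- matrix(rnorm(40), 20, 2)
  X[3, 1] <- NA
  expect_error(gm_statistics(X, rnorm(20)), "non-finite")
  expect_error(gm_statistics(matrix(rnorm(40), 20, 2), c(rnorm(19), Inf)),
               "non-finite")
})
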