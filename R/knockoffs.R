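#' Construct a first/second-moment model
#'
#' Container for the mean vector and covariance matrix used by the Gaussian
#' knockoff sampler. The covariance is symmetrized and clipped to positive
#' semi-definite (eigenvalues below zero, tolerated down to -1e-8, are set
#' to zero).
#'
#' @param mu length-p mean vector.
#' @param Sigma p-by-p covariance matrix.
#' @param source `"known"`, `"mle"`, or `"shrinkage"`.
#' @return An object of class `"moment_model"`.
#' @export
moment_model <- function(mu, Sigma, source = c("known", "mle", "shrinkage")) {
  source <- match.arg(source)
  p <- length(mu)
  stopifnot(is.matrix(Sigma), nrow(Sigma) == p, ncol(Sigma) == p)
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    warning("covariance has markedly negative eigenvalues; clipping to PSD",
            call. = FALSE)
  }
  if (min(ev$values) < 0) {
    Sigma <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  structure(list(mu = as.numeric(mu), Sigma = Sigma, source = source),
            class = "moment_model")
}

#' @export
print.moment_model <- function(x, ...) {
  cat(sprintf("Moment model (%s): p = %d\n", x$source, length(x$mu)))
  invisible(x)
}

#' Estimate first and second moments of a design
#'
#' `"mle"` returns the sample mean and sample covariance. `"shrinkage"`
#' returns a James-Stein-type linear shrinkage estimate that pulls the
#' sample correlations toward zero (diagonal target) with the analytic
#' intensity of the Schafer-Strimmer/Ledoit-Wolf family,
#' \eqn{\hat\lambda = \sum_{i \ne j} \widehat{Var}(r_{ij}) /
#' \sum_{i \ne j} r_{ij}^2} clamped to `[0, 1]`; variances are left
#' unshrunk. The shrinkage estimate is full rank even when `p > n`, which
#' stabilizes the second-order knockoff construction.
#'
#' @param X n-by-p design matrix.
#' @param estimator `"mle"` or `"shrinkage"`.
#' @return A [moment_model()].
#' @export
#' @examples
#' X <- matrix(rnorm(200 * 10), 200, 10)
#' estimate_moments(X, "shrinkage")
estimate_moments <- function(X, estimator = c("mle", "shrinkage")) {
  check_finite_matrix(X, "X")
  estimator <- match.arg(estimator)
  n <- nrow(X)
  if (n < 2) stop("need at least two rows", call. = FALSE)
  mu <- colMeans(X)
  v <- apply(X, 2, var)
  if (estimator == "shrinkage" && any(v < 1e-12)) {
    warning("constant column(s); variance floored at 1e-12", call. = FALSE)
    v <- pmax(v, 1e-12)
  }
  if (estimator == "mle") {
    return(moment_model(mu, cov(X), source = "mle"))
  }
  xs <- sweep(sweep(X, 2, mu), 2, sqrt(v), "/")
  C <- crossprod(xs)                     # (n-1) * correlation matrix
  R <- C / (n - 1)
  A <- crossprod(xs^2)
  VarR <- n / (n - 1)^3 * (A - C^2 / n)
  diag(VarR) <- 0
  off <- R; diag(off) <- 0
  denom <- sum(off^2)
  lambda <- if (denom > 0) min(1, max(0, sum(VarR) / denom)) else 1
  Rsh <- (1 - lambda) * R
  diag(Rsh) <- 1
  Sigma <- Rsh * tcrossprod(sqrt(v))
  out <- moment_model(mu, Sigma, source = "shrinkage")
  out$shrinkage_intensity <- lambda
  out
}

#' Solve for the knockoff s-vector
#'
#' The vector \eqn{s \ge 0} controls how different the knockoffs are from
#' the originals, subject to \eqn{2\Sigma - \mathrm{diag}(s) \succeq 0}.
#' The problem is solved on the correlation scale and rescaled on return.
#' `"equi"` uses the equicorrelated solution
#' \eqn{s_j = \min(2 \lambda_{\min}(R), 1)}; `"sdp"` maximizes
#' \eqn{\sum_j s_j} subject to \eqn{0 \le s_j \le 1} and the semidefinite
#' constraint, via cyclic coordinate ascent (each coordinate's exact upper
#' bound is \eqn{1/(M^{-1})_{jj}} for \eqn{M = 2R - \mathrm{diag}(s)}).
#' If the ascent fails numerically it falls back to the equicorrelated
#' solution with a warning.
#'
#' @param Sigma p-by-p positive semi-definite covariance matrix.
#' @param method `"equi"` (default) or `"sdp"`.
#' @return An object of class `"s_vector"`: list with `s` (covariance
#'   scale), `s_corr` (correlation scale), and `method`.
#' @export
#' @examples
#' solve_s(matrix(c(1, 0.8, 0.8, 1), 2, 2))$s # 0.4, 0.4
solve_s <- function(Sigma, method = c("equi", "sdp")) {
  method <- match.arg(method)
  stopifnot(is.matrix(Sigma), nrow(Sigma) == ncol(Sigma))
  p <- nrow(Sigma)
  v <- diag(Sigma)
  if (any(v <= 0)) stop("'Sigma' must have positive diagonal", call. = FALSE)
  R <- cov2cor(Sigma)
  if (method == "equi") {
    lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    s_corr <- rep(min(2 * max(lmin, 0), 1), p)
  } else {
    s_corr <- tryCatch(solve_s_sdp(R), error = function(e) {
      warning("SDP coordinate ascent failed (", conditionMessage(e),
              "); falling back to equicorrelated", call. = FALSE)
      lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      rep(min(2 * max(lmin, 0), 1), p)
    })
  }
  structure(list(s = s_corr * v, s_corr = s_corr, method = method),
            class = "s_vector")
}

# Cyclic coordinate ascent for max sum(s) s.t. 0 <= s <= 1,
# 2R - diag(s) PSD. A slack factor keeps M strictly positive definite so
# the sampler's conditional covariance stays well-behaved.
solve_s_sdp <- function(R, sweeps = 20L, slack = 1 - 1e-6) {
  p <- nrow(R)
  lmin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  # start strictly inside the feasible set; the ascent pushes outward
  s <- rep(min(2 * max(lmin, 0), 1) * 0.5, p)
  for (it in seq_len(sweeps)) {
    changed <- 0
    M <- 2 * R - diag(s, p)
    Minv <- solve(M)
    for (j in seq_len(p)) {
      room <- slack / Minv[j, j]
      new_sj <- min(1, s[j] + room)
      if (new_sj > s[j] + 1e-10) {
        delta <- new_sj - s[j]
        # Sherman-Morrison update of Minv for M <- M - delta e_j e_j'
        mj <- Minv[, j]
        denom <- 1 - delta * Minv[j, j]
        if (denom <= 1e-12) next
        Minv <- Minv + (delta / denom) * tcrossprod(mj)
        s[j] <- new_sj
        changed <- changed + delta
      }
    }
    if (changed < 1e-8) break
  }
  # verify feasibility
  ev <- min(eigen(2 * R - diag(s, p), symmetric = TRUE,
                  only.values = TRUE)$values)
  if (ev < -1e-8) stop("coordinate ascent left the feasible set")
  s
}

#' Sample exact-Gaussian knockoffs
#'
#' Draws knockoff rows from the conditional Gaussian
#' \deqn{\tilde X \mid X \sim N\big(X - (X - \mu)\Sigma^{-1}\mathrm{diag}(s),
#'   \; 2\,\mathrm{diag}(s) - \mathrm{diag}(s)\Sigma^{-1}\mathrm{diag}(s)\big),}
#' so the joint second moments of \eqn{[X, \tilde X]} converge to the
#' swap-exchangeable block matrix
#' \eqn{[[\Sigma, \Sigma - \mathrm{diag}(s)],
#'       [\Sigma - \mathrm{diag}(s), \Sigma]]}. The second-order knockoff
#' construction is this sampler applied with moments estimated by
#' [estimate_moments()].
#'
#' @param X n-by-p design matrix.
#' @param model a [moment_model()].
#' @param s an [solve_s()] result (or nonnegative numeric vector on the
#'   covariance scale).
#' @param seed integer RNG seed.
#' @return An n-by-p matrix of knockoffs (`s = 0` returns `X` itself).
#' @export
sample_gaussian_knockoffs <- function(X, model, s, seed) {
  check_finite_matrix(X, "X")
  stopifnot(inherits(model, "moment_model"))
  svec <- if (inherits(s, "s_vector")) s$s else as.numeric(s)
  p <- ncol(X)
  stopifnot(length(svec) == p, all(svec >= 0))
  Sigma <- model$Sigma
  SinvS <- tryCatch({
    ch <- chol(Sigma)
    backsolve(ch, forwardsolve(t(ch), diag(svec, p)))
  }, error = function(e) {
    warning("covariance numerically singular; ridge-regularized solve",
            call. = FALSE)
    ridge <- 1e-8 * mean(diag(Sigma))
    solve(Sigma + diag(ridge, p), diag(svec, p))
  })
  mu_cond <- X - sweep(X, 2, model$mu) %*% SinvS
  V <- diag(2 * svec, p) - diag(svec, p) %*% SinvS
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  set.seed(seed)
  Z <- matrix(rnorm(nrow(X) * p), nrow(X), p)
  mu_cond + Z %*% t(L)
}

#' Knockoff statistics from a cross-validated lasso
#'
#' Fits a single cross-validated lasso of `y` on the concatenation
#' \eqn{[X, \tilde X]} and returns
#' \eqn{W_j = |\hat\beta_j(\lambda)| - |\hat\beta_{j+p}(\lambda)|} at the
#' cross-validation-selected penalty. The 2p columns are randomly
#' interleaved before fitting (and restored afterwards) so coordinate-order
#' tie-breaking inside the solver cannot systematically favor originals
#' over knockoffs.
#'
#' @param X n-by-p design matrix.
#' @param Xtilde n-by-p knockoff matrix.
#' @param y length-n response.
#' @param nfolds cross-validation folds (default 10).
#' @param seed integer seed for the column interleaving and fold draw.
#' @return An object of class `"knockoff_stats"`: list with `W` (length-p),
#'   `lambda` (selected penalty), and `seed`.
#' @export
knockoff_statistics <- function(X, Xtilde, y, nfolds = 10, seed = NULL) {
  check_finite_matrix(X, "X")
  check_finite_matrix(Xtilde, "Xtilde")
  if (!all(is.finite(y))) stop("'y' contains non-finite values",
                               call. = FALSE)
  if (!all(dim(X) == dim(Xtilde))) {
    stop("'X' and 'Xtilde' must have the same shape", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)",
                                 call. = FALSE)
  p <- ncol(X); n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(2L * p)
  A <- cbind(X, Xtilde)[, perm, drop = FALSE]
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cv <- glmnet::cv.glmnet(A, y, foldid = foldid)
  b_perm <- drop(coef(cv, s = "lambda.min"))[-1]
  b <- numeric(2L * p)
  b[perm] <- b_perm
  W <- abs(b[seq_len(p)]) - abs(b[p + seq_len(p)])
  structure(list(W = W, lambda = cv$lambda.min, seed = seed),
            class = "knockoff_stats")
}

#' @export
print.knockoff_stats <- function(x, ...) {
  cat(sprintf("Knockoff statistics (p = %d, lambda = %.4g)\n",
              length(x$W), x$lambda))
  cat("  W summary:\n")
  print(summary(x$W))
  invisible(x)
}
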