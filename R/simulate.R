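#' Specify a benchmark design matrix
#'
#' Describes an n-by-p design whose columns share one marginal family and a
#' compound-symmetric correlation structure. Non-Gaussian correlated columns
#' are produced through a Gaussian copula: compound-symmetric latent normals
#' are transformed by their CDF and then by the target inverse CDF (Uniform,
#' Poisson) or thresholded into Hardy-Weinberg genotype bins (`snp_like`).
#' The latent correlation is calibrated numerically so the realized Pearson
#' correlation (squared correlation for genotypes) hits the target, which
#' preserves the marginals exactly.
#'
#' The Cauchy family has no finite moments and is supported only at
#' `rho = 0`; its default parameterization is location 0, scale 1.
#'
#' @param family one of `"gaussian"`, `"uniform"`, `"poisson"`, `"cauchy"`,
#'   `"snp_like"`.
#' @param n number of rows (samples), at least 2.
#' @param p number of columns (variables), at least 2.
#' @param rho target pairwise correlation in `[0, 0.9]`. For `snp_like`
#'   designs it is the centre of the adjacent-pair linkage-disequilibrium
#'   (LD, squared correlation) band: `rho = 0.2` maps to LD 0.15-0.25 and
#'   so on, with `rho = 0` meaning LD below 0.05 (treated as independent).
#'   Override with `ld_band` for an explicit band.
#' @param rate Poisson rate (default 3).
#' @param location,scale Cauchy location and scale (defaults 0 and 1).
#' @param maf_range range minor-allele frequencies are drawn from
#'   (default `c(0.05, 0.5)`).
#' @param ld_band optional length-2 vector: target band for the adjacent-pair
#'   squared genotype correlation. Defaults to `rho^2 +- 0.05` (clamped to
#'   `[0, 1)`); a band entirely below 0.05 is treated as independence.
#' @return An object of class `"design_spec"`.
#' @export
#' @examples
#' design_spec("gaussian", n = 500, p = 1200, rho = 0)
#' design_spec("snp_like", n = 500, p = 300, rho = 0.4)
design_spec <- function(family = c("gaussian", "uniform", "poisson", "cauchy",
                                   "snp_like"),
                        n, p, rho = 0, rate = 3, location = 0, scale = 1,
                        maf_range = c(0.05, 0.5), ld_band = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 2, p >= 2)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 0.9) {
    stop("'rho' must be in [0, 0.9]", call. = FALSE)
  }
  if (family == "cauchy" && rho > 0) {
    stop("unsupported configuration: correlated Cauchy designs are not ",
         "defined (the family has no finite moments)", call. = FALSE)
  }
  if (family == "snp_like") {
    if (maf_range[1] <= 0.01 || maf_range[2] > 0.5) {
      stop("'maf_range' must lie within (0.01, 0.5]", call. = FALSE)
    }
    if (is.null(ld_band)) {
      ld_band <- if (rho == 0) c(0, 0.05) else
        pmin(pmax(c(rho - 0.05, rho + 0.05), 0), 1 - 1e-8)
    }
    if (ld_band[1] < 0 || ld_band[2] >= 1 || ld_band[1] > ld_band[2]) {
      stop("'ld_band' must be an increasing pair within [0, 1)",
           call. = FALSE)
    }
  } else {
    ld_band <- NULL
  }
  structure(
    list(family = family, n = as.integer(n), p = as.integer(p), rho = rho,
         rate = rate, location = location, scale = scale,
         maf_range = maf_range, ld_band = ld_band),
    class = "design_spec"
  )
}

#' Specify the sparse signal of a simulated regression
#'
#' `k` coefficients, placed uniformly at random, are drawn from
#' \eqn{N(0, \sigma_1^2)}; the rest are exactly zero. When `sigma1_sq` is
#' `NULL` it is calibrated by [calibrate_sigma1_sq()] so the linear predictor
#' accounts for `signal_fraction` of the outcome variance.
#'
#' @param k number of nonzero coefficients (default 60).
#' @param signal_fraction target proportion of outcome variance explained by
#'   the predictors (default 0.9).
#' @param sigma1_sq optional fixed effect-size variance; overrides the
#'   calibration.
#' @return An object of class `"signal_spec"`.
#' @export
signal_spec <- function(k = 60, signal_fraction = 0.9, sigma1_sq = NULL) {
  stopifnot(k >= 0)
  if (signal_fraction <= 0 || signal_fraction >= 1) {
    stop("'signal_fraction' must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(sigma1_sq) && sigma1_sq <= 0) {
    stop("'sigma1_sq' must be positive", call. = FALSE)
  }
  structure(list(k = as.integer(k), signal_fraction = signal_fraction,
                 sigma1_sq = sigma1_sq),
            class = "signal_spec")
}

# ---- Gaussian copula machinery ---------------------------------------------

# The discrete marginals (Poisson counts, genotype bins) are nondecreasing
# step functions of the latent normal: g(z) = sum_k 1{z > a_k} for sorted
# thresholds a. Their latent-normal cross moments reduce to orthant
# probabilities; integrating the analytic inner conditional
# E[h(Z2) | Z1 = z] = sum_l Phi((r z - b_l)/sqrt(1 - r^2)) on a fine grid
# is accurate where naive two-dimensional quadrature oscillates on the
# discontinuities.

# thresholds of the Poisson quantile transform (drops mass below 1e-14)
poisson_thresholds <- function(rate) {
  K <- qpois(1 - 1e-14, rate)
  qnorm(ppois(seq_len(K) - 1, rate))
}

# thresholds of the Hardy-Weinberg genotype binning at one MAF
snp_thresholds <- function(maf) {
  qnorm(c((1 - maf)^2, 1 - maf^2))
}

# Pearson correlation of two latent-threshold step variables at latent r.
step_output_cor <- function(a, b, r) {
  a <- sort(a); b <- sort(b)
  m1 <- sum(1 - pnorm(a))
  m2 <- sum(1 - pnorm(b))
  v1 <- sum((2 * seq_along(a) - 1) * (1 - pnorm(a))) - m1^2
  v2 <- sum((2 * seq_along(b) - 1) * (1 - pnorm(b))) - m2^2
  z <- seq(-8.5, 8.5, length.out = 1701L)
  gz <- findInterval(z, a)
  sh <- rowSums(pnorm(outer(r * z, b, "-") / sqrt(1 - r^2)))
  egh <- sum(dnorm(z) * gz * sh) * (z[2] - z[1])
  (egh - m1 * m2) / sqrt(v1 * v2)
}

# Marginal transform g for one column of a given family.
copula_transform <- function(spec, maf = NULL) {
  switch(spec$family,
    gaussian = identity,
    uniform  = pnorm,
    # clamp away from 1 so extreme quadrature nodes stay finite
    poisson  = function(z) qpois(pmin(pnorm(z), 1 - 1e-16), spec$rate),
    snp_like = {
      t1 <- qnorm((1 - maf)^2)
      t2 <- qnorm(1 - maf^2)
      function(z) (z > t1) + (z > t2)
    },
    stop("no copula transform for family ", spec$family)
  )
}

# Latent correlation achieving a target output correlation for one family
# (compound-symmetric continuous families).
calibrate_latent_rho <- function(spec, target) {
  if (target == 0) return(0)
  switch(spec$family,
    gaussian = return(target),
    uniform  = return(2 * sin(pi * target / 6)) # closed form for U(0,1)
  )
  a <- poisson_thresholds(spec$rate)
  uniroot(function(r) step_output_cor(a, a, r) - target,
          c(1e-6, 1 - 1e-6), tol = 1e-4)$root
}

# Latent correlation for one adjacent genotype pair hitting a target
# genotype correlation; returns the capped maximum (and achieved value)
# when the pair's MAF mismatch makes the target unreachable.
calibrate_snp_pair <- function(spec, maf1, maf2, target, cap = 0.999) {
  a <- snp_thresholds(maf1)
  b <- snp_thresholds(maf2)
  f <- function(r) step_output_cor(a, b, r)
  top <- f(cap)
  if (top <= target) {
    return(list(latent = cap, achieved = top, feasible = FALSE))
  }
  r <- uniroot(function(r) f(r) - target, c(1e-6, cap), tol = 1e-4)$root
  list(latent = r, achieved = target, feasible = TRUE)
}

# ---- Generators -------------------------------------------------------------

#' Generate a benchmark design matrix
#'
#' Draws an n-by-p matrix with the marginal family and compound-symmetric
#' correlation described by `spec` (see [design_spec()] for the copula
#' construction). Identical `(spec, seed)` pairs give identical output.
#'
#' @param spec a [design_spec()].
#' @param seed integer RNG seed.
#' @return An n-by-p numeric matrix. For `snp_like` designs the drawn
#'   minor-allele frequencies are attached as `attr(X, "maf")` and entries
#'   are genotypes in `{0, 1, 2}`.
#' @export
#' @examples
#' X <- generate_design(design_spec("poisson", n = 200, p = 20), seed = 1)
generate_design <- function(spec, seed) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(seed)
  n <- spec$n; p <- spec$p
  if (spec$family == "cauchy") {
    return(matrix(rcauchy(n * p, spec$location, spec$scale), n, p))
  }
  if (spec$family == "snp_like") return(generate_snp(spec))
  rl <- calibrate_latent_rho(spec, spec$rho)
  Z <- matrix(rnorm(n * p), n, p)
  if (rl > 0) Z <- sqrt(rl) * rnorm(n) + sqrt(1 - rl) * Z
  switch(spec$family,
    gaussian = Z,
    uniform  = pnorm(Z),
    poisson  = qpois(pnorm(Z), spec$rate)
  )
}

# SNP-like genotypes from a latent Markov (AR-type) chain. Adjacent pairs
# get an individually calibrated latent correlation so their genotype
# squared correlation lands at the LD-band midpoint. High r2 between two
# loci is only attainable when their allele frequencies are similar, so for
# correlated bands the MAFs follow a reflected random walk (step sd 0.03)
# over `maf_range` instead of iid uniform draws; for the independence band
# they are iid uniform. Assumes set.seed() has been called.
generate_snp <- function(spec) {
  n <- spec$n; p <- spec$p
  independent <- spec$ld_band[2] <= 0.05
  target <- if (independent) 0 else sqrt(mean(spec$ld_band))
  if (independent) {
    maf <- runif(p, spec$maf_range[1], spec$maf_range[2])
  } else {
    steps <- c(runif(1, spec$maf_range[1], spec$maf_range[2]),
               rnorm(p - 1, 0, 0.03))
    w <- cumsum(steps)
    # reflect into the MAF range
    lo <- spec$maf_range[1]; hi <- spec$maf_range[2]
    per <- 2 * (hi - lo)
    w <- (w - lo) %% per
    maf <- lo + ifelse(w > (hi - lo), per - w, w)
  }
  a <- numeric(p - 1)        # latent adjacent correlations
  adj_cor <- numeric(p - 1)  # achieved adjacent genotype correlations
  infeasible <- integer(0)
  if (target > 0) {
    for (j in seq_len(p - 1)) {
      cal <- calibrate_snp_pair(spec, maf[j], maf[j + 1], target)
      a[j] <- cal$latent
      adj_cor[j] <- cal$achieved
      if (!cal$feasible) infeasible <- c(infeasible, j)
    }
    if (length(infeasible)) {
      warning(sprintf(
        "LD band unreachable for %d adjacent pair(s) (MAF mismatch): %s",
        length(infeasible),
        paste(head(infeasible, 10L), collapse = ", ")), call. = FALSE)
    }
  }
  E <- matrix(rnorm(n * p), n, p)
  Z <- E
  if (target > 0) {
    for (j in 2:p) Z[, j] <- a[j - 1] * Z[, j - 1] +
        sqrt(1 - a[j - 1]^2) * E[, j]
  }
  G <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    g <- copula_transform(spec, maf[j])
    G[, j] <- g(Z[, j])
  }
  attr(G, "maf") <- maf
  attr(G, "adj_cor") <- adj_cor
  attr(G, "ld_infeasible") <- infeasible
  G
}

#' Generate a SNP-like genotype matrix
#'
#' Convenience wrapper around [generate_design()] for the `snp_like` family:
#' entries are 0/1/2 genotype counts in Hardy-Weinberg proportions at
#' minor-allele frequencies drawn from `spec$maf_range`, with adjacent-pair
#' squared correlation (LD) calibrated into `spec$ld_band`.
#'
#' @inheritParams generate_design
#' @return An n-by-p integer-valued matrix with a `"maf"` attribute.
#' @export
generate_snp_design <- function(spec, seed) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$family != "snp_like") {
    stop("'spec' must have family \"snp_like\"", call. = FALSE)
  }
  generate_design(spec, seed)
}

# Population variance of one column (vector of length p for snp_like).
column_variances <- function(spec, maf = NULL) {
  switch(spec$family,
    gaussian = rep(1, spec$p),
    uniform  = rep(1 / 12, spec$p),
    poisson  = rep(spec$rate, spec$p),
    # robust scale proxy: squared (IQR / 1.349); Cauchy IQR = 2 * scale
    cauchy   = rep((2 * spec$scale / 1.349)^2, spec$p),
    snp_like = {
      if (is.null(maf)) {
        a <- spec$maf_range[1]; b <- spec$maf_range[2]
        em <- (a + b) / 2; em2 <- (b - a)^2 / 12 + em^2
        rep(2 * (em - em2), spec$p)
      } else 2 * maf * (1 - maf)
    }
  )
}

#' Calibrate the effect-size variance for a target signal fraction
#'
#' With noise variance 1 and `k` effects drawn from \eqn{N(0, \sigma_1^2)},
#' the expected variance explained by the predictors is
#' \eqn{E[\beta^\top \Sigma \beta] = \sigma_1^2 \sum_{j \in S} \Sigma_{jj}},
#' so a target fraction \eqn{f} of outcome variance requires
#' \deqn{\sigma_1^2 = \frac{f}{1 - f} \cdot
#'       \frac{\sigma_\epsilon^2}{\sum_{j \in S} \mathrm{Var}(x_j)}.}
#' For the Cauchy family, whose variance is undefined, the column variance
#' is replaced by a robust scale proxy (squared IQR / 1.349) and the result
#' is flagged with `attr(, "robust_proxy")`.
#'
#' @param spec a [design_spec()].
#' @param signal a [signal_spec()].
#' @param support optional integer support; needed only when column
#'   variances differ across columns (SNP-like designs with known MAFs).
#' @param maf optional per-column minor-allele frequencies.
#' @return Positive scalar \eqn{\sigma_1^2}.
#' @export
#' @examples
#' sp <- design_spec("gaussian", 500, 1200)
#' calibrate_sigma1_sq(sp, signal_spec(k = 60, signal_fraction = 0.9)) # 0.15
calibrate_sigma1_sq <- function(spec, signal, support = NULL, maf = NULL) {
  stopifnot(inherits(spec, "design_spec"), inherits(signal, "signal_spec"))
  f <- signal$signal_fraction
  v <- column_variances(spec, maf)
  total <- if (is.null(support)) signal$k * mean(v) else sum(v[support])
  if (total <= 0) stop("support carries no variance", call. = FALSE)
  out <- (f / (1 - f)) * 1 / total
  if (spec$family == "cauchy") attr(out, "robust_proxy") <- TRUE
  out
}

#' Simulate a sparse linear-model dataset
#'
#' Generates the design by [generate_design()], places `k` causal variables
#' uniformly at random, draws their effects from \eqn{N(0, \sigma_1^2)} with
#' \eqn{\sigma_1^2} calibrated per [calibrate_sigma1_sq()], and returns
#' \eqn{y = X\beta + \epsilon} with \eqn{\epsilon \sim N(0, I_n)}.
#'
#' @param spec a [design_spec()].
#' @param signal a [signal_spec()].
#' @param seed integer RNG seed; identical inputs reproduce the dataset
#'   bit for bit.
#' @return An object of class `"sim_dataset"`: list with `X`, `y`, `beta`,
#'   `support`, `sigma1_sq`, `spec`, `signal`, `seed`, `maf` (SNP designs),
#'   and `moments` (the true [moment_model()] implied by the generator;
#'   `NULL` for Cauchy).
#' @export
#' @examples
#' ds <- simulate_dataset(design_spec("gaussian", 200, 50),
#'                        signal_spec(k = 5), seed = 7)
simulate_dataset <- function(spec, signal, seed) {
  stopifnot(inherits(spec, "design_spec"), inherits(signal, "signal_spec"))
  if (signal$k > spec$p) stop("'k' cannot exceed 'p'", call. = FALSE)
  X <- generate_design(spec, derive_seed(seed, 1L))
  maf <- attr(X, "maf")
  set.seed(derive_seed(seed, 2L))
  p <- spec$p
  support <- if (signal$k > 0) sort(sample.int(p, signal$k)) else integer(0)
  beta <- numeric(p)
  sigma1 <- signal$sigma1_sq
  if (signal$k > 0) {
    if (is.null(sigma1)) {
      sigma1 <- as.numeric(calibrate_sigma1_sq(spec, signal, support, maf))
    }
    beta[support] <- rnorm(signal$k, 0, sqrt(sigma1))
  } else {
    sigma1 <- 0
  }
  eps <- rnorm(spec$n)
  y <- as.numeric(X %*% beta) + eps
  moments <- if (spec$family == "cauchy") NULL else true_moments(spec, maf)
  structure(
    list(X = X, y = y, beta = beta, support = support, sigma1_sq = sigma1,
         spec = spec, signal = signal, seed = seed, maf = maf,
         moments = moments),
    class = "sim_dataset"
  )
}

#' Moment model implied by a design specification
#'
#' The exact mean vector and covariance matrix of the generated columns:
#' compound-symmetric on the correlation scale at the requested `rho`
#' (for genotypes, at the correlation whose square is the LD-band midpoint),
#' with the family's marginal mean and variance on the diagonal. Used as the
#' "known distribution" input of the exact-Gaussian knockoff construction.
#'
#' @param spec a [design_spec()] with finite-variance family.
#' @param maf per-column minor-allele frequencies (required for `snp_like`).
#' @return A [moment_model()] with `source = "known"`.
#' @export
true_moments <- function(spec, maf = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$family == "cauchy") {
    stop("the Cauchy family has no defined moment model", call. = FALSE)
  }
  p <- spec$p
  mu <- switch(spec$family,
    gaussian = rep(0, p),
    uniform  = rep(0.5, p),
    poisson  = rep(spec$rate, p),
    snp_like = {
      if (is.null(maf)) stop("'maf' required for snp_like", call. = FALSE)
      2 * maf
    }
  )
  v <- column_variances(spec, maf)
  sdv <- sqrt(v)
  if (spec$family == "snp_like") {
    r <- if (spec$ld_band[2] <= 0.05) 0 else sqrt(mean(spec$ld_band))
    # genotype correlations decay multiplicatively along the Markov chain
    R <- r^abs(outer(seq_len(p), seq_len(p), `-`))
    Sigma <- R * tcrossprod(sdv)
  } else {
    Sigma <- spec$rho * tcrossprod(sdv)
    diag(Sigma) <- v
  }
  moment_model(mu, Sigma, source = "known")
}

# ---- Dataset I/O ------------------------------------------------------------

#' Write / read a simulated dataset as TSV plus a JSON sidecar
#'
#' `write_dataset()` stores `X` and `y` in a single headered TSV
#' (`<prefix>_data.tsv`, response in column `y`) and all metadata (spec,
#' signal, seed, support, beta, sigma1_sq, MAFs) in `<prefix>_meta.json`.
#' SNP-like designs can additionally be exported as a transposed genotype
#' table (rows = variants, columns = samples) via `genotype_table = TRUE`.
#' `read_dataset()` restores the `"sim_dataset"` object.
#'
#' @param ds a `"sim_dataset"`.
#' @param prefix file path prefix.
#' @param genotype_table also write `<prefix>_genotypes.tsv` (SNP designs).
#' @return `write_dataset()` returns `prefix` invisibly; `read_dataset()`
#'   returns a `"sim_dataset"`.
#' @export
write_dataset <- function(ds, prefix, genotype_table = FALSE) {
  stopifnot(inherits(ds, "sim_dataset"))
  df <- as.data.frame(ds$X)
  names(df) <- paste0("x", seq_len(ncol(ds$X)))
  df$y <- ds$y
  write.table(df, paste0(prefix, "_data.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(
    spec = unclass(ds$spec), signal = unclass(ds$signal), seed = ds$seed,
    support = ds$support, beta = ds$beta, sigma1_sq = ds$sigma1_sq,
    maf = ds$maf
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (genotype_table) {
    if (ds$spec$family != "snp_like") {
      stop("genotype table export needs a snp_like design", call. = FALSE)
    }
    gt <- t(ds$X)
    dimnames(gt) <- list(paste0("variant", seq_len(nrow(gt))),
                         paste0("sample", seq_len(ncol(gt))))
    write.table(gt, paste0(prefix, "_genotypes.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
  }
  invisible(prefix)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(prefix) {
  df <- read.table(paste0(prefix, "_data.tsv"), header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  y <- df$y
  X <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  dimnames(X) <- NULL
  sp <- meta$spec
  spec <- design_spec(sp$family, sp$n, sp$p, sp$rho, rate = sp$rate,
                      location = sp$location, scale = sp$scale,
                      maf_range = sp$maf_range,
                      ld_band = sp$ld_band)
  sig <- signal_spec(meta$signal$k, meta$signal$signal_fraction,
                     meta$signal$sigma1_sq)
  maf <- meta$maf
  if (!is.null(maf)) attr(X, "maf") <- maf
  moments <- if (spec$family == "cauchy") NULL else true_moments(spec, maf)
  structure(
    list(X = X, y = y, beta = meta$beta, support = as.integer(meta$support),
         sigma1_sq = meta$sigma1_sq, spec = spec, signal = sig,
         seed = meta$seed, maf = maf, moments = moments),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d x %d %s design (rho = %g)\n",
              x$spec$n, x$spec$p, x$spec$family, x$spec$rho))
  cat(sprintf("  %d causal variables, sigma1^2 = %.4g\n",
              length(x$support), x$sigma1_sq))
  invisible(x)
}
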