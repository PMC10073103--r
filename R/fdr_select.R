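#' FDR-controlled variable selection
#'
#' Fits one of the implemented selection procedures to a design matrix and
#' response and applies the shared symmetric-statistic threshold at target
#' FDR level `q`:
#'
#' \describe{
#'   \item{`"gm"`}{Gaussian mirror: per-variable mirror pairs
#'     \eqn{x_j \pm c_j z_j} and statistics
#'     \eqn{M_j = |\hat\beta_j^+ + \hat\beta_j^-| -
#'                |\hat\beta_j^+ - \hat\beta_j^-|}.}
#'   \item{`"mx_gaussian"`}{Model-X knockoffs from a known Gaussian model:
#'     requires `moments` (mean and covariance of the design distribution).}
#'   \item{`"mx_second_order"`}{Second-order Model-X knockoffs: moments are
#'     estimated from `x` (`cov_estimator`, shrinkage by default) and fed to
#'     the same exact-Gaussian sampler.}
#' }
#'
#' @param x n-by-p numeric design matrix.
#' @param y length-n numeric response.
#' @param method `"gm"`, `"mx_gaussian"`, or `"mx_second_order"`.
#' @param q target FDR level in (0, 1), default 0.1.
#' @param offset 0 (default, plain FDP estimator) or 1 (conservative
#'   knockoff+ variant).
#' @param moments a [moment_model()] for `"mx_gaussian"`.
#' @param cov_estimator moment estimator for `"mx_second_order"`:
#'   `"shrinkage"` (default) or `"mle"`.
#' @param s_method s-vector construction, `"equi"` (default) or `"sdp"`.
#' @param nfolds cross-validation folds for lasso fits.
#' @param seed integer seed governing all method randomness (mirror
#'   perturbations or knockoff sampling, column interleaving, folds).
#' @param ... further arguments passed to [gm_statistics()] (e.g. `regime`,
#'   `standardize`).
#' @return An object of class `"fdr_select"`: list with `statistics`
#'   (length-p vector of \eqn{M_j} or \eqn{W_j}), `threshold`
#'   (\eqn{T_q}), `selected` (integer indices), `method`, `q`, `offset`,
#'   `detail` (the underlying `"mirror_result"` or `"knockoff_stats"`),
#'   and `call`.
#' @seealso [selection_threshold()], [gm_statistics()],
#'   [knockoff_statistics()]
#' @export
#' @examples
#' ds <- simulate_dataset(design_spec("gaussian", 200, 50),
#'                        signal_spec(k = 5), seed = 1)
#' fit <- fdr_select(ds$X, ds$y, method = "gm", q = 0.1, seed = 2)
#' print(fit)
#' all(ds$support %in% fit$selected)
fdr_select <- function(x, y,
                       method = c("gm", "mx_gaussian", "mx_second_order"),
                       q = 0.1, offset = 0, moments = NULL,
                       cov_estimator = c("shrinkage", "mle"),
                       s_method = c("equi", "sdp"),
                       nfolds = 10, seed = NULL, ...) {
  method <- match.arg(method)
  cov_estimator <- match.arg(cov_estimator)
  s_method <- match.arg(s_method)
  x <- as.matrix(x)
  check_finite_matrix(x, "x")
  detail <- switch(method,
    gm = gm_statistics(x, y, nfolds = nfolds, seed = seed, ...),
    mx_gaussian = {
      if (is.null(moments)) {
        stop("'mx_gaussian' needs a known moment model; supply 'moments' ",
             "or use method = \"mx_second_order\"", call. = FALSE)
      }
      mx_statistics(x, y, moments, s_method, nfolds, seed)
    },
    mx_second_order = {
      mom <- estimate_moments(x, cov_estimator)
      mx_statistics(x, y, mom, s_method, nfolds, seed)
    }
  )
  stats <- if (method == "gm") detail$M else detail$W
  sel <- selection_threshold(stats, q = q, offset = offset)
  structure(
    list(statistics = stats, threshold = sel$threshold,
         selected = sel$selected, method = method, q = q, offset = offset,
         detail = detail, call = match.call()),
    class = "fdr_select"
  )
}

# knockoff pipeline shared by mx_gaussian / mx_second_order
mx_statistics <- function(x, y, moments, s_method, nfolds, seed) {
  s <- solve_s(moments$Sigma, method = s_method)
  xt <- sample_gaussian_knockoffs(x, moments, s,
                                  seed = derive_seed(seed %||% 0L, 11L))
  ks <- knockoff_statistics(x, xt, y, nfolds = nfolds,
                            seed = derive_seed(seed %||% 0L, 12L))
  ks$s <- s
  ks$moments_source <- moments$source
  ks
}

#' @export
print.fdr_select <- function(x, ...) {
  lab <- c(gm = "Gaussian mirror",
           mx_gaussian = "Model-X knockoffs (exact Gaussian)",
           mx_second_order = "Model-X knockoffs (second order)")[x$method]
  cat(lab, "selection\n")
  cat(sprintf("  target FDR q = %g%s\n", x$q,
              if (x$offset == 1) " (conservative offset)" else ""))
  cat(sprintf("  threshold T_q = %s\n", format(x$threshold, digits = 4)))
  cat(sprintf("  selected %d of %d variables\n",
              length(x$selected), length(x$statistics)))
  invisible(x)
}

#' @export
summary.fdr_select <- function(object, ...) {
  out <- list(fit = object,
              stat_summary = summary(object$statistics),
              top = head(order(object$statistics, decreasing = TRUE), 10L))
  class(out) <- "summary.fdr_select"
  out
}

#' @export
print.summary.fdr_select <- function(x, ...) {
  print(x$fit)
  cat("\nStatistic summary:\n")
  print(x$stat_summary)
  cat("\nTop variables by statistic:\n")
  df <- data.frame(index = x$top,
                   statistic = x$fit$statistics[x$top],
                   selected = x$top %in% x$fit$selected)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fdr_select <- function(object, ...) {
  stats <- object$statistics
  names(stats) <- paste0("x", seq_along(stats))
  stats
}

#' Plot selection statistics against variable index
#'
#' Displays the per-variable statistics with the selection threshold
#' \eqn{\pm T_q} and highlights the selected variables.
#'
#' @param x an `"fdr_select"` object.
#' @param ... passed to [plot()].
#' @export
plot.fdr_select <- function(x, ...) {
  s <- x$statistics
  plot(seq_along(s), s, pch = 16, cex = 0.6, col = "grey50",
       xlab = "variable index",
       ylab = if (x$method == "gm") expression(M[j]) else expression(W[j]),
       ...)
  if (is.finite(x$threshold)) {
    abline(h = c(-x$threshold, x$threshold), lty = 2, col = "steelblue")
  }
  if (length(x$selected)) {
    points(x$selected, s[x$selected], pch = 16, col = "firebrick")
  }
  legend("topright", legend = c("selected", "threshold"), bty = "n",
         pch = c(16, NA), lty = c(NA, 2),
         col = c("firebrick", "steelblue"))
  invisible(x)
}
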