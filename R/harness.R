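#' Run one simulation replicate
#'
#' Generates a dataset, applies one selection method at target FDR `q`, and
#' scores the selection against the true support. The replicate is fully
#' reproducible from `seed`: the dataset and the method's internal
#' randomness use deterministically derived sub-seeds.
#'
#' The exact-Gaussian knockoff (`"mx_gaussian"`) needs a Gaussian model of
#' the design distribution. With `mx_moments = "auto"` (default) it uses
#' the generator's true moment model when the family really is Gaussian,
#' and otherwise fits a Gaussian model by maximum likelihood (sample mean
#' and covariance) — the design distribution is then genuinely unknown to
#' the method, and when `n < p` the fitted covariance is singular, which
#' collapses the knockoffs onto the originals and drives both FDR and
#' power toward zero. `"generator"` and `"mle"` force either choice. On a
#' Cauchy design no moment model exists and the replicate is recorded as
#' missing (`NA` scores), matching the convention of reporting a dash for
#' undefined method/family cells.
#'
#' @param spec a [design_spec()].
#' @param signal a [signal_spec()].
#' @param method `"gm"`, `"mx_gaussian"`, or `"mx_second_order"`.
#' @param q target FDR level.
#' @param seed integer replicate seed.
#' @param offset threshold offset, 0 or 1.
#' @param cov_estimator covariance estimator for `"mx_second_order"`.
#' @param s_method s-vector construction.
#' @param nfolds cross-validation folds.
#' @param mx_moments moment source for `"mx_gaussian"`: `"auto"`
#'   (default), `"generator"`, or `"mle"` (see Details).
#' @return A one-row data frame: design/method descriptors plus
#'   `n_selected`, `fdp`, `power`.
#' @export
run_replicate <- function(spec, signal, method, q = 0.1, seed = 1,
                          offset = 0, cov_estimator = "shrinkage",
                          s_method = "equi", nfolds = 10,
                          mx_moments = c("auto", "generator", "mle")) {
  mx_moments <- match.arg(mx_moments)
  base <- data.frame(family = spec$family, n = spec$n, p = spec$p,
                     rho = spec$rho, method = method, q = q, seed = seed)
  if (method == "mx_gaussian" && spec$family == "cauchy") {
    return(cbind(base, data.frame(n_selected = NA_integer_,
                                  fdp = NA_real_, power = NA_real_)))
  }
  ds <- simulate_dataset(spec, signal, derive_seed(seed, 101L))
  moments <- ds$moments
  if (method == "mx_gaussian") {
    use_mle <- mx_moments == "mle" ||
      (mx_moments == "auto" && spec$family != "gaussian")
    if (use_mle) moments <- estimate_moments(ds$X, "mle")
  }
  fit <- suppressWarnings(
    fdr_select(ds$X, ds$y, method = method, q = q, offset = offset,
               moments = moments, cov_estimator = cov_estimator,
               s_method = s_method, nfolds = nfolds,
               seed = derive_seed(seed, 202L)))
  cbind(base, evaluate_selection(fit$selected, ds$support, spec$p))
}

#' Run a Monte-Carlo experiment grid
#'
#' Executes `reps` replicates of every cell in a grid of design families,
#' sample sizes, dimensions, correlations, methods and target FDR levels.
#' Replicate seeds are derived deterministically from `master_seed` and the
#' cell's position, so cells can be run in any order (or re-run alone) with
#' identical results. Cells that fail are recorded with `NA` scores and the
#' error message is collected in `attr(, "failed")`.
#'
#' @param families character vector of design families.
#' @param n,p,rho,methods,q vectors defining the grid (crossed).
#' @param k number of causal variables (default 60).
#' @param signal_fraction target proportion of explained variance.
#' @param reps Monte-Carlo replicates per cell (default 100).
#' @param master_seed integer master seed.
#' @param ... further arguments passed to [run_replicate()].
#' @return A data frame of class `"results_table"`, one row per
#'   (cell, replicate).
#' @export
#' @examples
#' \donttest{
#' res <- run_experiment("gaussian", n = 200, p = 60, rho = 0,
#'                       methods = "gm", q = 0.1, k = 10, reps = 3,
#'                       master_seed = 1)
#' summarize_results(res)
#' }
run_experiment <- function(families, n, p, rho = 0, methods = "gm",
                           q = 0.1, k = 60, signal_fraction = 0.9,
                           reps = 100, master_seed = 1, ...) {
  grid <- expand.grid(family = families, n = n, p = p, rho = rho,
                      method = methods, q = q,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * reps)
  failed <- character(0)
  idx <- 0L
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    spec_ok <- !(g$family == "cauchy" && g$rho > 0)
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      seed <- derive_seed(master_seed, cell, r)
      rows[[idx]] <- tryCatch({
        if (!spec_ok) stop("correlated Cauchy design undefined")
        spec <- design_spec(g$family, g$n, g$p, g$rho)
        sig <- signal_spec(k = min(k, g$p), signal_fraction)
        rr <- run_replicate(spec, sig, g$method, q = g$q, seed = seed, ...)
        rr$replicate <- r
        rr
      }, error = function(e) {
        failed <<- c(failed, sprintf("cell %d rep %d: %s", cell, r,
                                     conditionMessage(e)))
        data.frame(family = g$family, n = g$n, p = g$p, rho = g$rho,
                   method = g$method, q = g$q, seed = seed,
                   n_selected = NA_integer_, fdp = NA_real_,
                   power = NA_real_, replicate = r)
      })
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", "data.frame")
  attr(out, "failed") <- failed
  out
}

#' Aggregate per-replicate results into benchmark-style tables
#'
#' Averages the per-replicate false discovery proportions and powers over
#' replicates within each cell and attaches Monte-Carlo standard errors.
#' `shape = "long"` returns the tidy aggregate; `"fdr_by_family"` /
#' `"power_by_family"` pivot to distributions-by-method tables (rows nested
#' in target FDR level or sample size); `"by_rho"` pivots to correlation
#' levels by (family, method). Cells with no finite replicates are shown
#' as `"-"` in the wide shapes.
#'
#' @param results a `"results_table"` from [run_experiment()].
#' @param shape output layout (see Details).
#' @return A data frame.
#' @export
summarize_results <- function(results,
                              shape = c("long", "fdr_by_family",
                                        "power_by_family", "by_rho")) {
  shape <- match.arg(shape)
  stopifnot(is.data.frame(results))
  if (!nrow(results)) {
    warning("empty results table", call. = FALSE)
    return(data.frame())
  }
  keys <- c("family", "n", "p", "rho", "method", "q")
  agg <- do.call(rbind, lapply(
    split(results, results[keys], drop = TRUE),
    function(d) {
      ok <- is.finite(d$fdp)
      data.frame(
        d[1, keys],
        reps = sum(ok),
        fdr = if (any(ok)) mean(d$fdp[ok]) else NA_real_,
        fdr_se = if (sum(ok) > 1) sd(d$fdp[ok]) / sqrt(sum(ok)) else NA_real_,
        power = if (any(is.finite(d$power))) {
          mean(d$power[is.finite(d$power)])
        } else NA_real_,
        power_se = if (sum(is.finite(d$power)) > 1) {
          sd(d$power[is.finite(d$power)]) /
            sqrt(sum(is.finite(d$power)))
        } else NA_real_
      )
    }))
  rownames(agg) <- NULL
  if (shape == "long") return(agg)
  value <- if (shape == "power_by_family") "power" else "fdr"
  rowvar <- if (shape == "by_rho") "rho" else "family"
  cols <- if (shape == "by_rho") {
    paste(agg$family, agg$method, sep = ":")
  } else as.character(agg$method)
  fmt <- function(x) if (length(x) && is.finite(x[1])) {
    sprintf("%.3f", x[1])
  } else "-"
  qs <- sort(unique(agg$q))
  rows <- sort(unique(agg[[rowvar]]))
  labs <- sort(unique(cols))
  res <- do.call(rbind, lapply(qs, function(qlev) {
    do.call(rbind, lapply(rows, function(rv) {
      cells <- vapply(labs, function(cl) {
        fmt(agg[[value]][agg$q == qlev & agg[[rowvar]] == rv & cols == cl])
      }, character(1))
      df <- data.frame(q = qlev, row = as.character(rv),
                       t(cells), check.names = FALSE)
      names(df)[2] <- rowvar
      df
    }))
  }))
  rownames(res) <- NULL
  res
}

#' Map variants to contiguous gene blocks
#'
#' Assigns the `p` variants of a design to consecutive genes whose sizes are
#' drawn uniformly between `min_size` and `max_size`, mimicking candidate-
#' gene panels where each gene contributes a block of neighboring SNPs.
#'
#' @param p number of variants.
#' @param min_size,max_size gene size range (defaults 10 and 80).
#' @param seed integer RNG seed.
#' @return A factor of length `p` with levels `"gene1"`, `"gene2"`, ...
#' @export
make_gene_map <- function(p, min_size = 10, max_size = 80, seed = 1) {
  set.seed(seed)
  sizes <- integer(0)
  total <- 0L
  while (total < p) {
    s <- sample.int(max_size - min_size + 1L, 1L) + min_size - 1L
    sizes <- c(sizes, min(s, p - total))
    total <- total + sizes[length(sizes)]
  }
  factor(rep(paste0("gene", seq_along(sizes)), sizes),
         levels = paste0("gene", seq_along(sizes)))
}

#' Repeated-selection protocol over a fixed dataset
#'
#' Both the mirror and knockoff procedures are randomized (fresh
#' perturbations or knockoff draws), so on a fixed dataset the analysis is
#' repeated many times and each gene's selection frequency is recorded: a
#' gene counts as selected in one repeat if any of its variants is
#' selected, and genes below the `cutoff` frequency are deemed not
#' associated.
#'
#' @param dataset a `"sim_dataset"` (or any list with `X` and `y`).
#' @param gene_map factor or vector mapping every column of `X` to a gene.
#' @param method selection method passed to [fdr_select()].
#' @param q target FDR level (default 0.1).
#' @param repeats number of randomized repeats (default 100).
#' @param master_seed integer master seed; repeat r uses a derived seed.
#' @param cutoff association frequency cutoff (default 0.05).
#' @param ... further arguments passed to [fdr_select()].
#' @return A data frame with one row per gene: `gene`, `n_variants`,
#'   `frequency`, `associated`.
#' @export
repeated_selection_protocol <- function(dataset, gene_map, method = "gm",
                                        q = 0.1, repeats = 100,
                                        master_seed = 1, cutoff = 0.05,
                                        ...) {
  X <- dataset$X; y <- dataset$y
  if (length(gene_map) != ncol(X)) {
    stop("'gene_map' must label every column of X", call. = FALSE)
  }
  if (anyNA(gene_map)) stop("unmapped variant in 'gene_map'", call. = FALSE)
  if (repeats < 1) stop("'repeats' must be at least 1", call. = FALSE)
  gene_map <- as.factor(gene_map)
  genes <- levels(gene_map)
  hits <- setNames(numeric(length(genes)), genes)
  moments <- dataset$moments
  for (r in seq_len(repeats)) {
    fit <- fdr_select(X, y, method = method, q = q, moments = moments,
                      seed = derive_seed(master_seed, 303L, r), ...)
    if (length(fit$selected)) {
      sel_genes <- unique(gene_map[fit$selected])
      hits[as.character(sel_genes)] <- hits[as.character(sel_genes)] + 1
    }
  }
  freq <- hits / repeats
  data.frame(gene = genes,
             n_variants = as.integer(table(gene_map)[genes]),
             frequency = as.numeric(freq),
             associated = as.numeric(freq) >= cutoff,
             row.names = NULL)
}
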