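# fdrselect

Variable selection with false discovery rate (FDR) control for sparse
linear models, for biostatisticians and methodologists comparing
selection procedures on high-dimensional designs (genotype panels,
expression counts, and the like).

Two families of procedures are implemented on a shared inferential core:

* **Gaussian mirror (GM).** Each variable is perturbed into a pair
  x_j ± c_j z_j with a fresh Gaussian draw z_j, the model is refitted
  (OLS for p < n, cross-validated lasso otherwise), and the statistic

      M_j = |b_j^+ + b_j^-| − |b_j^+ − b_j^-|

  is symmetric about 0 for null variables once the scalar
  c_j = ‖(I − P₋j)x_j‖ / ‖(I − P₋j)z_j‖ decorrelates the pair.

* **Model-X knockoffs (MX).** A synthetic copy X̃ of the design is drawn
  from a Gaussian model of the rows so that [X, X̃] has swap-invariant
  second moments; a single cross-validated lasso on [X, X̃] gives

      W_j = |b_j(λ)| − |b_{j+p}(λ)|.

  The model is either known exactly (MX-G) or estimated from the data
  with a James–Stein-type shrinkage covariance (second-order knockoffs,
  MX-SO).

Both statistics are thresholded by the data-driven rule

    FDP̂(t) = (#{j : s_j ≤ −t} + offset) / max(#{j : s_j ≥ t}, 1),
    T_q = min{t > 0 : FDP̂(t) ≤ q},

selecting {j : s_j ≥ T_q}. A synthetic-data module generates the
benchmark designs (Gaussian / Uniform / Poisson / Cauchy marginals and
SNP-like 0/1/2 genotypes, compound-symmetric correlation or target LD
bands, 60 causal variables calibrated to 90% explained variance), and a
Monte-Carlo harness measures empirical FDR and power over experiment
grids. See the vignette in `vignettes/` for the models, calibration
details and design decisions.

## Worked example

```r
library(fdrselect)

spec <- design_spec("gaussian", n = 500, p = 200)
ds   <- simulate_dataset(spec, signal_spec(k = 60, signal_fraction = 0.9),
                         seed = 11)

fit <- fdr_select(ds$X, ds$y, method = "gm", q = 0.1, seed = 12)
print(fit)
#> Gaussian mirror selection
#>   target FDR q = 0.1
#>   threshold T_q = 0.07164
#>   selected 50 of 200 variables

evaluate_selection(fit$selected, ds$support, p = 200)
#>   n_selected  fdp     power
#> 1         50 0.12 0.7333333

mx <- fdr_select(ds$X, ds$y, method = "mx_second_order", q = 0.1, seed = 12)
evaluate_selection(mx$selected, ds$support, p = 200)
#>   n_selected        fdp     power
#> 1         45 0.02222222 0.7333333
```

Of the 60 truly causal variables the mirror recovers 44 (power 0.73)
with 6 false positives among 50 selections (realized FDP 0.12, targeted
at q = 0.1 — single-run FDP fluctuates around the target; the *rate* is
controlled in expectation). The second-order knockoff run selects 45
variables at the same power with one false positive. `plot(fit)` shows
the statistics with the selection threshold; `coef(fit)` returns them as
a named vector.

Experiment grids run through the harness:

```r
res <- run_experiment(c("gaussian", "poisson"), n = 500, p = 1200,
                      methods = c("gm", "mx_second_order"),
                      q = c(0.1, 0.2), reps = 100, master_seed = 1)
summarize_results(res, "fdr_by_family")
```

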