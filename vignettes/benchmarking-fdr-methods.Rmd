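---
title: "Mirror and knockoff selection with FDR control: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror and knockoff selection with FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdrselect)
```

## The problem

Biomarker discovery in high-dimensional regressions (genotypes,
transcript counts, proteomic panels) asks for a *set* of variables with a
guarantee on the expected fraction of false positives — the false
discovery rate (FDR) — rather than per-variable p-values, which are hard
to calibrate when the design is non-Gaussian, correlated, or wider than it
is tall. `fdrselect` implements two modern procedures that sidestep
p-values entirely by manufacturing *negative controls* for every variable
and exploiting the sign symmetry of a contrast statistic under the null:

* the **Gaussian mirror (GM)**, which perturbs one variable at a time, and
* the **Model-X knockoff filter (MX)**, which samples a synthetic copy of
  the whole design, in an exact-Gaussian (MX-G) and a second-order
  (MX-SO) variant.

Both feed a common thresholding rule, and the package ships a Monte-Carlo
harness that measures their empirical FDR and power on synthetic designs
spanning marginal families, dimensions and correlation strengths.

The data model throughout is the sparse linear model
$$ y = X\beta + \epsilon, \qquad \epsilon \sim N(0, I_n), $$
with $k$ nonzero coefficients (default 60) drawn from
$N(0, \sigma_1^2)$ and the rest exactly zero.

## The Gaussian mirror

For variable $j$, draw $z_j \sim N(0, I_n)$ and replace $x_j$ by the pair
$x_j^{\pm} = x_j \pm c_j z_j$. Refit the regression and form
$$ M_j = \lvert\hat\beta_j^+ + \hat\beta_j^-\rvert -
         \lvert\hat\beta_j^+ - \hat\beta_j^-\rvert . $$
For a null variable both coefficients hover near zero and $M_j$ is
symmetric about zero; for a causal variable both are dominated by the true
effect, so the sum dominates the difference and $M_j > 0$.

The scalar $c_j$ is what makes the null symmetry exact in the
ordinary-least-squares regime ($p < n$). We use
$$ c_j \;=\; \frac{\lVert (I - P_{-j})\, x_j \rVert}
                  {\lVert (I - P_{-j})\, z_j \rVert}, $$
with $P_{-j}$ the projector onto the other columns. A direct computation
of the OLS coefficient covariance (done in the package tests on small
designs) shows that at this value the pair $(\hat\beta_j^+,
\hat\beta_j^-)$ is exactly **uncorrelated**, equivalently
$\mathrm{Var}(\hat\beta_j^+ + \hat\beta_j^-) =
\mathrm{Var}(\hat\beta_j^+ - \hat\beta_j^-)$. Under Gaussian errors the
null pair $(\text{sum}, \text{difference})$ is then exchangeable, which
is precisely what makes $\lvert\text{sum}\rvert - \lvert\text{diff}\rvert$
symmetric about zero. We note for implementers that the condition is
sometimes written as "the covariance between sum and difference vanishes";
algebraically that cross-covariance is proportional to the inner product
of the residualized $x_j$ and $z_j$ and cannot be controlled by any
scalar, so the equal-variance/uncorrelated-pair condition above is the one
the scalar actually enforces — and the one we test.

Implementation notes:

* With one variable mirrored at a time, the $p$ OLS refits reduce to
  rank-one updates of a single factorization of $X$: the mirror span
  equals $\mathrm{span}(X_{-j}, x_j, z_j)$, so the pair coefficients are
  linear functions of the coefficients of $x_j$ and $z_j$ in the design
  $[X, z_j]$. `gm_statistics()` uses this path and the tests verify it
  against naive refits of the literal mirror design.
* When $p \ge n$ the model is refit with a cross-validated lasso on the
  mirror design, and the projector in $c_j$ is restricted to the active
  set of an initial lasso fit (with $j$ removed; empty active set gives
  $c_j = \lVert x_j\rVert / \lVert z_j \rVert$; active sets larger than
  $n - 2$ are truncated to the largest-coefficient members with a
  warning). Folds are drawn once per run and reused across the $p$ fits.
* Columns are standardized to unit standard deviation by default. Both
  members of a pair inherit their parent's scale, so $M_j$ is
  scale-consistent; standardization only equalizes the scale *across*
  variables, which matters because one threshold is applied to all of
  them.

## Model-X knockoffs

Given a Gaussian model $N(\mu, \Sigma)$ for the rows of $X$, knockoffs
are sampled from the conditional law
$$ \tilde X \mid X \sim N\!\big(X - (X - \mu)\Sigma^{-1}D_s,\;
   2D_s - D_s\Sigma^{-1}D_s\big), \qquad D_s = \mathrm{diag}(s), $$
so the joint second moments of $[X, \tilde X]$ form the swap-invariant
block matrix $\big[\begin{smallmatrix}\Sigma & \Sigma - D_s\\
\Sigma - D_s & \Sigma\end{smallmatrix}\big]$. The vector $s \ge 0$
(solved on the correlation scale, subject to $2\Sigma - D_s \succeq 0$)
controls how distinguishable knockoffs are from originals: $s = 0$ copies
the design exactly and destroys all power, larger $s$ decorrelates the
copy. `solve_s()` provides the equicorrelated solution
$s_j = \min(2\lambda_{\min}, 1)$ (default) and a coordinate-ascent
maximizer of $\sum_j s_j$ under the semidefinite constraint (`"sdp"`;
exact per-coordinate bound $1/(M^{-1})_{jj}$, equicorrelated fallback on
numerical failure).

A single cross-validated lasso on $[X, \tilde X]$ yields
$$ W_j = \lvert\hat\beta_j(\lambda)\rvert -
         \lvert\hat\beta_{j+p}(\lambda)\rvert, $$
symmetric about zero for nulls when the knockoffs are valid. The $2p$
columns are randomly interleaved before fitting and restored afterwards,
so coordinate-order tie-breaking in the solver cannot favor originals.

Two constructions differ only in where $(\mu, \Sigma)$ comes from:

* **MX-G (exact Gaussian)** requires a *known* model. In the harness this
  is meaningful only for the Gaussian family, where the generator's own
  moments are exact. For any other family the design law is genuinely
  unknown to the method, and `run_replicate()` hands MX-G a
  maximum-likelihood Gaussian fit (sample mean and covariance) by
  default (`mx_moments = "auto"`). This choice has a consequence worth
  stating plainly: when $n < p$ the fitted covariance is singular, the
  feasible $s$ collapses to (numerically) zero, knockoffs nearly
  duplicate the originals, and both FDR and power collapse toward zero.
  That collapse is a real property of plugging an MLE covariance into the
  exact-Gaussian construction, and the harness reproduces it by design;
  `mx_moments = "generator"` is available to study MX-G with oracle
  moments instead, where no collapse occurs.
* **MX-SO (second order)** estimates the moments from the data with a
  James–Stein-type linear shrinkage estimator
  (Schäfer–Strimmer/Ledoit–Wolf family, diagonal target): sample
  correlations are shrunk toward zero with the analytic intensity
  $\hat\lambda = \sum_{i\ne j}\widehat{\mathrm{Var}}(r_{ij}) /
  \sum_{i\ne j} r_{ij}^2$ (clamped to $[0,1]$), variances are left
  unshrunk with a $10^{-12}$ floor for constant columns. The estimate is
  full-rank even when $p > n$, which is exactly what keeps MX-SO usable
  at $n = 500$, $p = 1200$. The plain MLE is available
  (`cov_estimator = "mle"`) to reproduce the power dip when $n \approx p$.

At these benchmark sizes the shrinkage intensity for independent designs
is close to 1 for every marginal family we generate (the target is then
correct), so second-order knockoffs are near-independent of the originals
and MX-SO's power is essentially family-invariant. Pipelines that shrink
less, or not at all, can behave much worse on some families; the
covariance estimator is a first-class switch here for that reason.

## The selection rule

Both statistics share the estimator and threshold
$$ \widehat{\mathrm{FDP}}(t) =
   \frac{\#\{j : s_j \le -t\} + \text{offset}}
        {\#\{j : s_j \ge t\} \vee 1}, \qquad
   T_q = \min\{t > 0 : \widehat{\mathrm{FDP}}(t) \le q\}, $$
selecting $\{j : s_j \ge T_q\}$. Numerical conventions, fixed once:

* The search runs over the candidate set $\{|s_j| : s_j \ne 0\}$. The
  estimator is piecewise constant with jumps only at these magnitudes, so
  this is selection-equivalent to an exhaustive search over all positive
  $t$ (verified against a dense-grid minimizer in the tests); the
  reported $T_q$ is the smallest qualifying magnitude.
* Selection uses $\ge$, so ties at the threshold are all selected, and
  zero statistics are never selectable nor candidates.
* `offset = 0` (default) is the plain estimator; `offset = 1` is the
  conservative variant whose selections are provably FDR-controlling;
  offset-1 selections are always a subset of offset-0 selections. With
  very few selections the offset-0 estimator is noticeably
  anti-conservative — visible in the gene-protocol example below, where
  occasional false positives are expected and handled by the repetition
  frequency cutoff rather than per-run control.
* $T_q = +\infty$ (empty selection) when no candidate qualifies, e.g.
  when every statistic is negative or zero.

## The synthetic-data generator

`design_spec()` + `simulate_dataset()` emulate the benchmark conditions
the methods are compared under:

* **Marginals**: Gaussian $N(0,1)$, Uniform $U(0,1)$, Poisson(3), Cauchy,
  and SNP-like 0/1/2 genotypes with Hardy–Weinberg column frequencies at
  minor-allele frequencies (MAFs) drawn from $(0.05, 0.5)$ — inside the
  usual MAF $\ge 0.01$ analysis filter with a margin that keeps LD
  calibration feasible. One parameterization note: the Cauchy family is
  sometimes quoted with location/scale transposed as $C(1, 0)$, which is
  degenerate (scale 0); the generator exposes both parameters and
  defaults to the standard $C(0, 1)$.
* **Correlation**: compound-symmetric at pairwise level $\rho$. For
  non-Gaussian families a Gaussian copula is used — compound-symmetric
  latent normals pushed through the latent CDF and the target inverse
  CDF — with the latent correlation calibrated numerically so the
  *realized* Pearson correlation hits $\rho$ (closed form
  $2\sin(\pi\rho/6)$ for Uniform; for discrete marginals the
  cross-moment is computed from the threshold representation of the
  quantile transform, integrating the analytic conditional CDF sum on a
  fine grid — naive two-dimensional quadrature oscillates on the
  discontinuities and miscalibrates badly).
* **Genotype LD**: the correlation label maps to a band of adjacent-pair
  squared correlation (LD) centred at $\rho$ ($\rho = 0.2 \mapsto$ LD
  0.15–0.25, …), with LD $\le 0.05$ treated as independence. Genotypes
  use a latent Markov chain with a *per-adjacent-pair* calibrated latent
  correlation, because LD decays along a chromosome and because high
  $r^2$ between two loci is attainable only when their allele
  frequencies are similar. For correlated bands the MAFs therefore
  follow a reflected random walk (step sd 0.03) over the MAF range
  rather than iid uniform draws — iid MAFs make high-LD bands
  mathematically unreachable for most pairs. Pairs whose MAF mismatch
  still makes the band unreachable are capped at the achievable
  correlation and reported by index in a warning.
* **Signal calibration**: with effects $\beta_S \sim N(0, \sigma_1^2 I)$,
  $E[\beta^\top\Sigma\beta] = \sigma_1^2\sum_{j\in S}\Sigma_{jj}$, so a
  target explained-variance fraction $f$ (default 0.9) gives
  $\sigma_1^2 = \frac{f}{1-f}\cdot\sigma_\epsilon^2 \big/
  \sum_{j\in S}\mathrm{Var}(x_j)$; e.g. $\sigma_1^2 = 9/60 = 0.15$ for 60
  unit-variance Gaussian columns and $9/180 = 0.05$ for Poisson(3)
  columns. The Cauchy family has no variance; its calibration substitutes
  a robust scale proxy (squared IQR$/1.349$), flagged on the returned
  value, so Cauchy runs are interpretable only qualitatively.
* Support positions are uniform at random each replicate; columns are
  *not* standardized at generation — standardization is a fitting-stage
  option.

What the generator does **not** emulate: realistic LD block structure
(haplotypes, recombination hotspots), site-frequency spectra, genotype
missingness or QC artifacts, non-linear or interaction effects, and
non-Gaussian noise. Passing benchmarks here therefore demonstrates
correctness of the procedures under their stated assumptions, not
performance on real genomes.

## Reproducibility and problem sizes

Every stochastic step (design, effects, noise, mirror perturbations,
knockoff draws, fold assignments, column interleaving) is governed by an
integer seed; sub-seeds are derived by deterministic integer mixing so
experiment cells can run in any order — `run_experiment()` re-run with the
same master seed is bit-identical.

Monte-Carlo sizes are chosen so the whole suite runs on a desk machine:
knockoff cells at the full benchmark size ($n = 500$, $p = 1200$, 60
causal variables, 15–20 replicates), mirror cells in the OLS regime at
$p = 200$ (40–50 replicates). The lasso-regime mirror costs $p$
cross-validated lasso fits per replicate (hours at $p = 1200$), which is
an inherent cost of the one-at-a-time construction; its statistical
behavior is checked at reduced dimension instead, and the mirror's
full-dimension power is accordingly not asserted against fixed reference
values. Empirical FDR at nominal $q = 0.1$/$0.2$ is reproduced within
Monte-Carlo error in the regimes above; see `tests/testthat/` and
`scripts/acceptance.R` for every number the package actually computes.

## A worked gene-protocol example

Mirror perturbations and knockoff draws are random, so on a fixed dataset
the analysis is repeated and genes are scored by selection frequency —
a gene counts as hit when any of its variants is selected, and genes
below a 5% frequency are deemed not associated:

```{r gene-protocol, eval = FALSE}
spec <- design_spec("snp_like", n = 500, p = 300, rho = 0.2)
ds <- simulate_dataset(spec, signal_spec(k = 10), seed = 1)
map <- make_gene_map(300, seed = 2)
freq <- repeated_selection_protocol(ds, map, method = "gm", q = 0.1,
                                    repeats = 100, master_seed = 3)
head(freq[order(-freq$frequency), ])
```

## Known limitations

* GM in the lasso regime is computationally heavy by construction.
* The exact-Gaussian knockoff with MLE moments is reported as a benchmark
  condition, not a recommended estimator; with $n < p$ it is degenerate
  (see above). Use MX-SO, or shrinkage moments, in practice.
* FDR control at `offset = 0` is approximate for small candidate sets;
  use `offset = 1` when finite-sample guarantees matter.
* Cauchy designs violate the moment assumptions of every method here and
  are supported for qualitative robustness studies only.
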