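test_that("effect-size variance calibration matches the closed form", {
  # unit-variance columns: sigma1^2 = (0.9/0.1) / 60 = 0.15
  sp <- design_spec("gaussian", 500, 1200)
  expect_equal(calibrate_sigma1_sq(sp, signal_spec(60, 0.9)), 0.15)
  # Poisson(3) columns carry variance 3: 9 / 180 = 0.05
  sp <- design_spec("poisson", 500, 1200)
  expect_equal(calibrate_sigma1_sq(sp, signal_spec(60, 0.9)), 0.05)
  # f = 0.5 makes the ratio 1: sigma1^2 = 1 / sum(var)
  sp <- design_spec("gaussian", 500, 100)
  expect_equal(calibrate_sigma1_sq(sp, signal_spec(9, 0.5)), 1 / 9)
  # uniform variance 1/12
  sp <- design_spec("uniform", 500, 100)
  expect_equal(calibrate_sigma1_sq(sp, signal_spec(60, 0.9)),
               9 / (60 / 12))
  # Cauchy: robust proxy, flagged
  sp <- design_spec("cauchy", 500, 100)
  out <- calibrate_sigma1_sq(sp, signal_spec(10, 0.9))
  expect_true(attr(out, "robust_proxy"))
  expect_gt(out, 0)
})

test_that("generation is deterministic in (spec, seed)", {
  for (fam in c("gaussian", "poisson", "snp_like", "cauchy")) {
    sp <- design_spec(fam, 50, 12, if (fam %in% c("gaussian", "poisson"))
      0.4 else 0)
    a <- generate_design(sp, seed = 99)
    b <- generate_design(sp, seed = 99)
    expect_identical(a, b)
    expect_false(identical(a, generate_design(sp, seed = 100)))
  }
  ds1 <- simulate_dataset(design_spec("gaussian", 60, 20),
                          signal_spec(k = 4), seed = 5)
  ds2 <- simulate_dataset(design_spec("gaussian", 60, 20),
                          signal_spec(k = 4), seed = 5)
  expect_identical(ds1$X, ds2$X)
  expect_identical(ds1$y, ds2$y)
  expect_identical(ds1$support, ds2$support)
})

test_that("marginals match their nominal distributions at n = 2000", {
  n <- 2000
  X <- generate_design(design_spec("gaussian", n, 4), seed = 1)
  expect_gt(stats::ks.test(X[, 1], pnorm)$p.value, 0.01)
  expect_lt(abs(mean(X[, 2])), 0.1)
  expect_lt(abs(var(X[, 2]) - 1), 0.15)
  X <- generate_design(design_spec("uniform", n, 4), seed = 2)
  expect_gt(stats::ks.test(X[, 1], punif)$p.value, 0.01)
  X <- generate_design(design_spec("cauchy", n, 4), seed = 3)
  expect_gt(stats::ks.test(X[, 1], pcauchy)$p.value, 0.01)
  # discrete family: chi-square against Poisson(3) cell probabilities
  X <- generate_design(design_spec("poisson", n, 4), seed = 4)
  expect_lt(abs(mean(X[, 1]) - 3), 0.2)
  expect_lt(abs(var(X[, 1]) - 3), 0.4)
  tab <- table(factor(pmin(X[, 2], 9), levels = 0:9))
  pr <- c(dpois(0:8, 3), 1 - ppois(8, 3))
  expect_gt(stats::chisq.test(tab, p = pr)$p.value, 0.01)
})

test_that("compound-symmetric correlation is calibrated per family", {
  n <- 2000
  for (fam in c("gaussian", "uniform", "poisson")) {
    X <- generate_design(design_spec(fam, n, 25, rho = 0.5), seed = 11)
    cc <- cor(X)
    expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.5), 0.05)
  }
  X <- generate_design(design_spec("gaussian", n, 25, rho = 0.8), seed = 12)
  cc <- cor(X)
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.8), 0.05)
})

test_that("SNP designs respect HWE, the 0/1/2 alphabet and LD bands", {
  sp <- design_spec("snp_like", 4000, 40, rho = 0)
  X <- generate_design(sp, seed = 21)
  expect_true(all(X %in% 0:2))
  maf <- attr(X, "maf")
  expect_true(all(maf >= 0.05 & maf <= 0.5))
  # column genotype frequencies close to (1-m)^2, 2m(1-m), m^2
  j <- which.max(maf)
  m <- maf[j]
  frq <- tabulate(X[, j] + 1L, 3L) / nrow(X)
  expect_lt(max(abs(frq - c((1 - m)^2, 2 * m * (1 - m), m^2))), 0.03)
  # independence band: adjacent r2 below 0.05
  r2 <- sapply(1:39, function(k) cor(X[, k], X[, k + 1])^2)
  expect_lt(mean(r2), 0.05)
  # correlated bands: mean adjacent r2 inside band +- 0.05
  for (rho in c(0.2, 0.8)) {
    sp <- design_spec("snp_like", 2000, 40, rho = rho)
    X <- suppressWarnings(generate_design(sp, seed = 22))
    r2 <- sapply(1:39, function(k) cor(X[, k], X[, k + 1])^2)
    expect_gt(mean(r2), sp$ld_band[1] - 0.05)
    expect_lt(mean(r2), sp$ld_band[2] + 0.05)
  }
})

test_that("unreachable LD bands are reported with the failing pairs", {
  sp <- design_spec("snp_like", 200, 12, ld_band = c(0.9, 0.95))
  expect_warning(X <- generate_design(sp, seed = 31), "unreachable")
  expect_true(length(attr(X, "ld_infeasible")) > 0)
})

test_that("invalid configurations are rejected", {
  expect_error(design_spec("cauchy", 100, 10, rho = 0.2), "unsupported")
  expect_error(design_spec("gaussian", 100, 10, rho = 0.95), "0, 0.9")
  expect_error(design_spec("gaussian", 1, 10), "n >= 2")
  expect_error(signal_spec(10, 1.2), "0, 1")
  expect_error(simulate_dataset(design_spec("gaussian", 50, 10),
                                signal_spec(k = 20), seed = 1), "exceed")
})

test_that("k = 0 gives a pure-noise outcome", {
  ds <- simulate_dataset(design_spec("gaussian", 400, 10),
                         signal_spec(k = 0), seed = 8)
  expect_equal(drop(ds$X %*% ds$beta), rep(0, 400))
  expect_length(ds$support, 0)
  expect_lt(abs(var(ds$y) - 1), 0.2)
})

test_that("predictors explain the target fraction of outcome variance", {
  for (fam in c("gaussian", "poisson")) {
    frac <- sapply(1:30, function(r) {
      ds <- simulate_dataset(design_spec(fam, 500, 100),
                             signal_spec(k = 60, signal_fraction = 0.9),
                             seed = 500 + r)
      v <- var(drop(ds$X %*% ds$beta))
      v / (v + 1)
    })
    expect_lt(abs(mean(frac) - 0.9), 0.03)
  }
})

test_that("datasets round-trip through the TSV + JSON bundle", {
  dir <- tempfile(); dir.create(dir)
  ds <- simulate_dataset(design_spec("snp_like", 40, 15, rho = 0),
                         signal_spec(k = 3), seed = 77)
  pre <- file.path(dir, "snp")
  write_dataset(ds, pre, genotype_table = TRUE)
  expect_true(file.exists(paste0(pre, "_data.tsv")))
  expect_true(file.exists(paste0(pre, "_genotypes.tsv")))
  back <- read_dataset(pre)
  expect_equal(back$X, ds$X, ignore_attr = TRUE)
  expect_equal(back$y, ds$y)
  expect_equal(back$support, ds$support)
  expect_equal(back$beta, ds$beta)
  gt <- as.matrix(read.table(paste0(pre, "_genotypes.tsv"), header = TRUE,
                             row.names = 1, sep = "\t"))
  expect_equal(unname(t(gt)), unname(ds$X + 0), ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("true moment model matches the generator's structure", {
  sp <- design_spec("poisson", 100, 6, rho = 0.3)
  mm <- true_moments(sp)
  expect_equal(mm$mu, rep(3, 6))
  expect_equal(diag(mm$Sigma), rep(3, 6))
  expect_equal(mm$Sigma[1, 2], 0.3 * 3)
  expect_error(true_moments(design_spec("cauchy", 100, 6)), "Cauchy")
})
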