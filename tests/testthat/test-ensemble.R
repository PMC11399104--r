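test_that("absorbance-based ensemble DOL follows the labeling equation", {
  expect_equal(ensemble_dol(1.0, 0, 2e5, 1e5), 0)
  expect_equal(ensemble_dol(1.0, 0.5, 1e5, 1e5, correction_280 = 0), 0.5)
  expect_equal(ensemble_dol(1.05, 1.0, 1e5, 1e5, correction_280 = 0.05), 1.0)
  expect_error(ensemble_dol(0.05, 1.0, 1e5, 1e5, correction_280 = 0.1),
               "non-positive")
  expect_error(ensemble_dol(1, 1, -1, 1e5), "extinction")
})

test_that("pseudo-ensemble DOL is the mean label count of labeled molecules", {
  expect_equal(pseudo_ensemble_dol(c("1" = 1.0)), 1.0)
  expect_equal(pseudo_ensemble_dol(c("1" = 0.5, "2" = 0.5)), 1.5)
  expect_equal(pseudo_ensemble_dol(c("1" = 0.80, "2" = 0.09, "3" = 0.11)),
               1.31)
  expect_error(pseudo_ensemble_dol(c("1" = 0.5, "2" = 0.4)), "sum to 1")
  expect_error(pseudo_ensemble_dol(numeric(0)), "empty")
  expect_error(pseudo_ensemble_dol(c("0" = 1)), ">= 1")
})

test_that("the unlabeled fraction reproduces the antibody worked example", {
  # ensemble DOL 1.27 over all antibodies, 1.38 among labeled ones -> 8%
  f <- unlabeled_fraction(1.27, 1.38)
  expect_equal(f, 1 - 1.27 / 1.38, tolerance = 1e-12)
  expect_equal(dol_percent(f), 8)
  expect_equal(unlabeled_fraction(1.0, 1.0), 0)
  expect_equal(unlabeled_fraction(0.5, 1.0), 0.5)
  expect_error(unlabeled_fraction(1.4, 1.38), "inconsistent")
  expect_error(unlabeled_fraction(0, 1), "> 0")
})

test_that("ensemble, labeled-mean and unlabeled fraction are self-consistent", {
  set.seed(23)
  for (i in 1:20) {
    labeled_mean <- runif(1, 1, 3)
    unl <- runif(1, 0, 0.9)
    ens <- (1 - unl) * labeled_mean
    expect_equal(ens, (1 - unlabeled_fraction(ens, labeled_mean)) * labeled_mean,
                 tolerance = 1e-12)
  }
})

test_that("copy-number extrapolation divides by DOL with quadrature errors", {
  out <- copies_per_cluster(c(2, 4), 0.2)
  expect_equal(out$copies, c(10, 20))
  expect_equal(out$copies_se, c(0, 0))
  expect_equal(copies_per_cluster(c(3, 7), 1)$copies, c(3, 7))
  q <- copies_per_cluster(2.0, 0.167, dol_se = 0.017)
  expect_equal(q$copies, 11.976, tolerance = 1e-3)
  expect_equal(q$copies_se / q$copies, 0.1018, tolerance = 1e-3)
  expect_error(copies_per_cluster(1, 0), "dol")
  # homogeneity: scaling counts scales copies
  a <- copies_per_cluster(c(1, 2, 3), 0.25)
  b <- copies_per_cluster(3 * c(1, 2, 3), 0.25)
  expect_equal(b$copies, 3 * a$copies)
})

test_that("log-normal fits recover geometric means", {
  f <- fit_lognormal(rep(7, 10))
  expect_equal(f$geometric_mean, 7, tolerance = 1e-12)
  expect_equal(f$sigma_log, 0)
  expect_equal(f$se_geometric_mean, 0)
})

test_that("log-normal fit matches hand arithmetic and sampling theory", {
  expect_error(fit_lognormal(c(1, exp(2))), "at least 3")
  f <- fit_lognormal(c(1, exp(1), exp(2)))
  expect_equal(f$mu_log, 1, tolerance = 1e-12)
  expect_equal(f$geometric_mean, exp(1), tolerance = 1e-12)
  expect_error(fit_lognormal(c(1, -1, 2, 3)), "> 0")

  set.seed(24)
  n <- 1e4
  draws <- exp(rnorm(n, 3, 0.5))
  fs <- fit_lognormal(draws)
  expect_lt(abs(fs$mu_log - 3), 3 * 0.5 / sqrt(n))
  expect_lt(abs(fs$sigma_log - 0.5), 0.02)
})
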