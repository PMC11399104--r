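test_that("candidate detection finds isolated and resolvable emitters", {
  flat <- image2d(matrix(100, 64, 64), 160)
  expect_equal(nrow(detect_candidates(flat)), 0L)

  # one emitter at ~SNR 10
  img <- render_fixture(x_nm = 30 * 160, y_nm = 25 * 160, photons = 350,
                        n_frames = 10, seed = 3)
  cand <- detect_candidates(img)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand[1, "col"] - 0.5 - 30), 1.5)
  expect_lt(abs(cand[1, "row"] - 0.5 - 25), 1.5)

  # two emitters 10 px apart
  img2 <- render_fixture(x_nm = c(20, 30) * 160, y_nm = c(32, 32) * 160,
                         photons = 350, n_frames = 10, seed = 4)
  expect_equal(nrow(detect_candidates(img2)), 2L)
})

test_that("a noiseless Gaussian is fit to sub-millipixel accuracy", {
  px <- 160
  x0 <- 15.37; y0 <- 17.81; s0 <- 150 / px
  fx <- pnorm((1:32 - x0) / s0) - pnorm((0:31 - x0) / s0)
  fy <- pnorm((1:32 - y0) / s0) - pnorm((0:31 - y0) / s0)
  img <- image2d(matrix(100, 32, 32) + 300 * outer(fy, fx), px)
  locs <- fit_spots(img, detect_candidates(img), detection_settings())
  expect_equal(nrow(locs), 1L)
  expect_lt(abs(locs$x_nm / px - x0), 1e-3)
  expect_lt(abs(locs$y_nm / px - y0), 1e-3)
})

test_that("localization RMSE at 350 photons stays below 25 nm", {
  set.seed(12)
  n <- 24
  x <- runif(n, 8, 56) * 160
  y <- runif(n, 8, 56) * 160
  # spread emitters to avoid overlap in this precision test
  keep <- rep(TRUE, n)
  for (i in 2:n) {
    if (any(sqrt((x[1:(i - 1)] - x[i])^2 + (y[1:(i - 1)] - y[i])^2)[keep[1:(i - 1)]] < 1500)) {
      keep[i] <- FALSE
    }
  }
  x <- x[keep]; y <- y[keep]
  img <- render_fixture(x, y, photons = 350, n_frames = 1, seed = 13)
  locs <- localize_image(img)
  err <- vapply(seq_along(x), function(i) {
    min(sqrt((locs$x_nm - x[i])^2 + (locs$y_nm - y[i])^2))
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 25)
})

test_that("two overlapping emitters 300 nm apart are split by the multi-emitter refit", {
  img <- render_fixture(x_nm = c(30 * 160 - 150, 30 * 160 + 150),
                        y_nm = c(32, 32) * 160, photons = 2000,
                        n_frames = 10, seed = 6)
  cand <- detect_candidates(img)
  locs3 <- fit_spots(img, cand, detection_settings(max_emitters_per_fit = 3))
  expect_equal(nrow(locs3), 2L)
  locs1 <- fit_spots(img, cand, detection_settings(max_emitters_per_fit = 1))
  expect_equal(nrow(locs1), 1L)
})

test_that("recall and false positives meet the sparse-image bounds", {
  cfg <- sim_config(probe_density_um2 = 0.1, true_dol = 0,
                    unspec_density_um2 = 0)
  cell <- simulate_experiment(cfg, n_cells = 1, seed = 33)[[1]]
  gt <- cell$ground_truth$probes  # inside the cell, away from frame edges
  locs <- localize_image(cell$reference)
  m <- match_one_to_one(locs_from_xy(gt$x_nm, gt$y_nm), locs, 250)
  recall <- nrow(m$pairs) / nrow(gt)
  area <- 256^2 * 0.16^2
  fp <- (nrow(locs) - nrow(m$pairs)) / area
  expect_gte(recall, 0.95)
  expect_lte(fp, 0.01)
})

test_that("the PSF-width filter removes off-modal widths", {
  same <- locs_from_xy(1:50 * 100, 1:50 * 100, sigma_nm = 150)
  expect_equal(nrow(filter_by_sigma(same)), 50L)

  s <- c(rep(1.0, 100), 2.0) * 150
  locs <- locs_from_xy(seq_along(s) * 100, seq_along(s) * 100, sigma_nm = s)
  kept <- filter_by_sigma(locs, 0.5)
  expect_equal(nrow(kept), 100L)
  expect_true(all(kept$sigma_nm == 150))
  # count never increases
  expect_lte(nrow(kept), nrow(locs))
})

test_that("an 80/20 width mixture retains the narrow component", {
  set.seed(77)
  n <- 5000
  s <- c(rnorm(0.8 * n, 150, 5), rnorm(0.2 * n, 400, 20))
  locs <- locs_from_xy(seq_along(s), seq_along(s), sigma_nm = s)
  kept <- filter_by_sigma(locs, 0.5)
  expect_lt(abs(nrow(kept) / n - 0.8), 0.03)
})
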