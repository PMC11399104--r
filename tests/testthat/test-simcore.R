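test_that("cell region generator honors area, connectivity and determinism", {
  expect_equal(make_cell_region(c(32, 32), 1, seed = 1),
               matrix(1L, 32, 32))

  m1 <- make_cell_region(c(256, 256), 0.4, seed = 7)
  m2 <- make_cell_region(c(256, 256), 0.4, seed = 7)
  expect_identical(m1, m2)
  frac <- sum(m1) / length(m1)
  expect_gte(frac, 0.32)
  expect_lte(frac, 0.48)
  # single connected component, no holes
  expect_equal(max(EBImage::bwlabel(m1)), 1)
  expect_equal(as.integer(EBImage::fillHull(m1)), as.integer(m1))

  m3 <- make_cell_region(c(256, 256), 0.4, seed = 8)
  expect_false(identical(m1, m3))
  expect_error(make_cell_region(c(8, 256), 0.4, seed = 1), "16")
  expect_error(make_cell_region(c(64, 64), 0, seed = 1), "fraction")
})

test_that("probe placement follows Bernoulli labeling and Poisson counts", {
  mask <- matrix(1L, 140, 140)  # 140 px at 160 nm -> 501.8 um^2
  gt <- place_probes(mask, 0.2, 1, 0, 160, seed = 3)
  expect_true(all(gt$probes$has_target))
  expect_true(all(gt$probes$has_reference))

  gt0 <- place_probes(mask, 0.2, 0, 0, 160, seed = 3)
  expect_false(any(gt0$probes$has_target))
  expect_equal(nrow(gt0$unspecific), 0L)

  # Poisson mean = density x area ~ 100; 3 sd band
  n <- nrow(gt$probes)
  expect_lt(abs(n - 100.4), 3 * sqrt(100.4))
  # probes inside the mask
  expect_true(all(gt$probes$x_nm >= 0 & gt$probes$x_nm <= 140 * 160))

  expect_error(place_probes(matrix(0L, 32, 32), 0.1, 0.5, 0, 160, seed = 1),
               "empty")
})

test_that("labeled fraction converges to the true DOL (binomial bound)", {
  mask <- matrix(1L, 256, 256)
  for (dol in c(0.3, 0.7)) {
    gt <- place_probes(mask, 0.5, dol, 0, 160, seed = 11)
    n <- nrow(gt$probes)
    expect_gte(n, 500)
    frac <- mean(gt$probes$has_target)
    expect_lt(abs(frac - dol), 3 * sqrt(dol * (1 - dol) / n))
  }
})

test_that("background-only rendering reproduces the camera model mean", {
  mask <- matrix(1L, 64, 64)
  gt <- place_probes(mask, 0, 0, 0, 160, seed = 1)
  cam <- camera_model(gain = 1, offset = 100, read_noise = 0, qe = 0.9)
  img <- render_channel(gt, "reference", photophysics(), cam,
                        psf_sigma_nm = 150, n_frames = 10,
                        background_photons = 12, seed = 5)
  expected <- 100 + 0.9 * 12
  sem <- sd(img$pixels) / sqrt(length(img$pixels))
  expect_lt(abs(mean(img$pixels) - expected), 3 * sem)
})

test_that("a rendered bright emitter refits to the configured PSF width", {
  img <- render_fixture(x_nm = 5120, y_nm = 5120, photons = 5000,
                        psf_sigma_nm = 150, seed = 2)
  locs <- fit_spots(img, detect_candidates(img), detection_settings())
  expect_equal(nrow(locs), 1L)
  expect_lt(abs(locs$sigma_nm - 150) / 150, 0.05)
})

test_that("blinking visibility matches the duty cycle of the on/off times", {
  phys <- photophysics(on_time = 0.025, off_time = 0.01, bleach_constant = 0)
  duty <- 0.025 / (0.025 + 0.01)
  expect_equal(phys$duty_cycle, duty)
  set.seed(42)
  vis <- prodolr:::visible_frames(2000, phys, 20L)
  frac <- mean(vis) / 20
  expect_lt(abs(frac - duty), 3 * sqrt(duty * (1 - duty) / (2000 * 20)))
})

test_that("rendered photon budget matches the emitter total within shot noise", {
  n_emit <- 25
  set.seed(9)
  xy <- 160 * (8 + runif(2 * n_emit) * 48)  # well inside a 64 px frame
  mask <- matrix(1L, 64, 64)
  gt <- place_probes(mask, 0, 0, 0, 160, seed = 1)
  gt$probes <- data.frame(x_nm = xy[1:n_emit], y_nm = xy[-(1:n_emit)],
                          has_reference = TRUE, has_target = FALSE)
  phys <- photophysics(on_time = 1, off_time = 0, bleach_constant = 0,
                       photons_per_s = 350)
  cam <- camera_model(gain = 1, offset = 0, read_noise = 0, qe = 1)
  n_frames <- 15
  img <- render_channel(gt, "reference", phys, cam, 150, n_frames,
                        background_photons = 0, seed = 31)
  total <- sum(img$pixels) * n_frames
  expected <- n_emit * n_frames * 350  # duty 1, no bleaching, qe 1
  expect_lt(abs(total - expected), 5 * sqrt(expected) + 0.001 * expected)
})

test_that("experiment simulation is deterministic and applies the chromatic map", {
  cfg <- small_sim_config()
  a <- simulate_experiment(cfg, n_cells = 2, seed = 5)
  b <- simulate_experiment(cfg, n_cells = 2, seed = 5)
  expect_identical(a[[1]]$reference$pixels, b[[1]]$reference$pixels)
  expect_identical(a[[2]]$target$pixels, b[[2]]$target$pixels)
  expect_false(identical(a[[1]]$ground_truth$probes,
                         a[[2]]$ground_truth$probes))

  # translation-only chromatic offset moves every doubly-labeled probe by
  # exactly the configured shift
  cfg_t <- small_sim_config(chromatic_shift_nm = c(120, 80),
                            chromatic_rotation_deg = 0,
                            chromatic_scale = c(1, 1))
  cell <- simulate_experiment(cfg_t, n_cells = 1, seed = 5)[[1]]
  gt <- cell$ground_truth
  both <- gt$probes[gt$probes$has_target, c("x_nm", "y_nm")]
  moved <- apply_affine(gt$chromatic_transform, as.matrix(both))
  disp <- moved - as.matrix(both)
  expect_equal(colMeans(disp), c(120, 80), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identity chromatic map: target truth coincides with reference truth
  cfg_i <- small_sim_config(chromatic_shift_nm = c(0, 0),
                            chromatic_rotation_deg = 0,
                            chromatic_scale = c(1, 1))
  cell_i <- simulate_experiment(cfg_i, n_cells = 1, seed = 5)[[1]]
  gt_i <- cell_i$ground_truth
  both_i <- gt_i$probes[gt_i$probes$has_target, c("x_nm", "y_nm")]
  moved_i <- apply_affine(gt_i$chromatic_transform, as.matrix(both_i))
  expect_equal(moved_i, as.matrix(both_i), tolerance = 1e-9,
               ignore_attr = TRUE)
})
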