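test_that("affine decomposition round-trips shear-free transforms", {
  tr <- affine_from_params(shift_nm = c(240, -80), rotation_deg = 1.25,
                           scale = c(1.01, 0.99))
  d <- decompose_affine(tr)
  expect_equal(d$shift_nm, c(240, -80), tolerance = 1e-9)
  expect_equal(d$rotation_deg, 1.25, tolerance = 1e-9)
  expect_equal(d$scale, c(1.01, 0.99), tolerance = 1e-9)
  back <- prodolr:::recompose_affine(d)
  expect_equal(back$m, tr$m, tolerance = 1e-6)
})

test_that("transform application, inversion and composition behave as a group", {
  set.seed(3)
  locs <- locs_from_xy(runif(20, 0, 4e4), runif(20, 0, 4e4))
  expect_equal(as.data.frame(apply_transform(locs, affine_identity())),
               as.data.frame(locs))
  shifted <- apply_transform(locs, affine_from_params(shift_nm = c(100, -50)))
  expect_equal(shifted$x_nm, locs$x_nm + 100)
  expect_equal(shifted$y_nm, locs$y_nm - 50)
  tr <- affine_from_params(c(500, 200), 2, c(1.02, 0.98))
  round_trip <- apply_transform(apply_transform(locs, tr), invert_affine(tr))
  expect_equal(round_trip$x_nm, locs$x_nm, tolerance = 1e-6)
  expect_equal(round_trip$y_nm, locs$y_nm, tolerance = 1e-6)
})

test_that("identical point sets register to the identity", {
  set.seed(5)
  locs <- locs_from_xy(runif(80, 0, 4e4), runif(80, 0, 4e4))
  est <- estimate_affine(locs, locs)
  expect_true(est$qc$accepted)
  expect_equal(est$transform$m, affine_identity()$m, tolerance = 1e-9)
  expect_equal(est$qc$rms_residual_nm, 0, tolerance = 1e-9)
})

test_that("a known transform is recovered from jittered points", {
  set.seed(6)
  n <- 200
  p <- cbind(runif(n, 0, 4e4), runif(n, 0, 4e4))
  truth <- affine_from_params(shift_nm = c(1.5 * 160, 0), rotation_deg = 1,
                              scale = c(1.01, 1.01))
  q <- apply_affine(truth, p) + matrix(rnorm(2 * n, 0, 10), n, 2)
  # estimate maps target onto reference: reference = truth(p), target = p
  est <- estimate_affine(locs_from_xy(q[, 1], q[, 2]),
                         locs_from_xy(p[, 1], p[, 2]))
  d <- decompose_affine(est$transform)
  expect_lt(abs(d$shift_nm[1] / 160 - 1.5), 0.1)
  expect_lt(abs(d$shift_nm[2] / 160 - 0), 0.1)
  expect_lt(abs(d$rotation_deg - 1), 0.1)
  expect_lt(max(abs(d$scale - 1.01)), 0.005)
  expect_true(est$qc$accepted)
})

test_that("noiseless registration is exact (equivariance)", {
  set.seed(7)
  p <- cbind(runif(40, 0, 4e4), runif(40, 0, 4e4))
  truth <- affine_from_params(c(300, -120), 2.5, c(1.03, 0.97))
  q <- apply_affine(truth, p)
  est <- estimate_affine(locs_from_xy(q[, 1], q[, 2]),
                         locs_from_xy(p[, 1], p[, 2]))
  expect_equal(est$transform$m, truth$m, tolerance = 1e-6)
})

test_that("sets under 50 emitters are excluded by quality control", {
  set.seed(8)
  locs <- locs_from_xy(runif(30, 0, 4e4), runif(30, 0, 4e4))
  est <- estimate_affine(locs, locs)
  expect_false(est$qc$accepted)
})

test_that("quality gates trigger strictly above the published thresholds", {
  ok <- function(...) prodolr:::qc_accept(...)
  expect_true(ok(50, c(3, 0), 0, 0))          # shift exactly 3 px stays
  expect_false(ok(50, c(3 + 1e-6, 0), 0, 0))  # ">3 pixels" excluded
  expect_true(ok(50, c(0, 0), 5, 0))
  expect_false(ok(50, c(0, 0), 5.0001, 0))
  expect_false(ok(50, c(0, 0), -5.0001, 0))
  expect_true(ok(50, c(0, 0), 0, 0.05))
  expect_false(ok(50, c(0, 0), 0, 0.0501))
  expect_true(ok(50, c(0, 0), 0, 0))
  expect_false(ok(49, c(0, 0), 0, 0))
})

test_that("pooling averages decomposed parameters over accepted transforms", {
  set.seed(9)
  locs <- locs_from_xy(runif(60, 0, 4e4), runif(60, 0, 4e4))
  one <- estimate_affine(locs, locs)
  expect_equal(pool_transforms(list(one))$m, one$transform$m)

  mk <- function(shift_px) {
    list(transform = affine_from_params(shift_nm = shift_px * 160),
         qc = list(accepted = TRUE))
  }
  pooled <- pool_transforms(list(mk(c(1, 0)), mk(c(3, 0))))
  expect_equal(decompose_affine(pooled)$shift_nm, c(2, 0) * 160,
               tolerance = 1e-9)
  expect_error(pool_transforms(list(list(transform = affine_identity(),
                                         qc = list(accepted = FALSE)))),
               "identity")
})

test_that("pooling noisy estimates beats the median single estimate", {
  set.seed(10)
  truth <- affine_from_params(c(200, -100), 0.5, c(1.005, 0.995))
  err_of <- function(tr) {
    d <- decompose_affine(tr); dt <- decompose_affine(truth)
    sqrt(sum((d$shift_nm - dt$shift_nm)^2)) / 160 +
      abs(d$rotation_deg - dt$rotation_deg) + sum(abs(d$scale - dt$scale))
  }
  wins <- 0
  for (rep in 1:30) {
    ests <- lapply(1:10, function(i) {
      p <- cbind(runif(60, 0, 4e4), runif(60, 0, 4e4))
      q <- apply_affine(truth, p) + matrix(rnorm(120, 0, 30), 60, 2)
      estimate_affine(locs_from_xy(q[, 1], q[, 2]),
                      locs_from_xy(p[, 1], p[, 2]))
    })
    pooled_err <- err_of(pool_transforms(ests))
    single_err <- median(vapply(ests, function(e) err_of(e$transform),
                                numeric(1)))
    if (pooled_err < single_err) wins <- wins + 1
  }
  expect_gte(wins, 22)  # pooling should win clearly more often than not
})
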