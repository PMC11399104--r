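test_that("one-to-one matching handles trivial configurations", {
  a <- locs_from_xy(c(0, 1000), c(0, 0))
  b <- locs_from_xy(c(50000, 60000), c(50000, 50000))
  expect_equal(nrow(match_one_to_one(a, b, 100)$pairs), 0L)

  m <- match_one_to_one(a, a, 10)
  expect_equal(nrow(m$pairs), 2L)
  expect_equal(m$pairs$distance_nm, c(0, 0))
  expect_equal(length(m$unmatched_ref_ids), 0L)
})

test_that("matching equals exhaustive enumeration on a crossing configuration", {
  # refs and targets interleaved so greedy nearest-first would err
  ref <- cbind(c(0, 2, 4, 6, 8), rep(0, 5))
  tgt <- cbind(c(1.1, 3.2, 5.1, 7.2, 9.3), rep(0, 5))
  rl <- locs_from_xy(ref[, 1], ref[, 2])
  tl <- locs_from_xy(tgt[, 1], tgt[, 2])
  for (tol in c(1.15, 1.3, 2, 5)) {
    m <- match_one_to_one(rl, tl, tol)
    want <- brute_force_match(ref, tgt, tol)
    expect_equal(nrow(m$pairs), unname(want["count"]))
    expect_equal(sum(m$pairs$distance_nm), unname(want["cost"]),
                 tolerance = 1e-9)
  }
})

test_that("matched pair count is monotone in the tolerance", {
  set.seed(14)
  rl <- locs_from_xy(runif(60, 0, 1e4), runif(60, 0, 1e4))
  tl <- locs_from_xy(runif(45, 0, 1e4), runif(45, 0, 1e4))
  counts <- vapply(c(50, 100, 200, 400, 800, 1600),
                   function(t) nrow(match_one_to_one(rl, tl, t)$pairs),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the 90-degree rotation null behaves geometrically", {
  fs <- c(8000, 8000)
  set.seed(15)
  locs <- locs_from_xy(runif(50, 100, 7900), runif(50, 100, 7900))
  r4 <- rotate_for_null(rotate_for_null(rotate_for_null(
    rotate_for_null(locs, fs), fs), fs), fs)
  expect_equal(r4$x_nm, locs$x_nm, tolerance = 1e-6)
  expect_equal(r4$y_nm, locs$y_nm, tolerance = 1e-6)
  expect_equal(nrow(rotate_for_null(locs, fs)), nrow(locs))

  center <- locs_from_xy(4000, 4000)
  rc <- rotate_for_null(center, fs)
  expect_equal(c(rc$x_nm, rc$y_nm), c(4000, 4000))

  # explicit rotation matrix about the center for (W/4, H/2)
  pt <- locs_from_xy(2000, 4000)
  rp <- rotate_for_null(pt, fs)
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  want <- as.numeric(R %*% (c(2000, 4000) - 4000) + 4000)
  expect_equal(c(rp$x_nm, rp$y_nm), want, tolerance = 1e-9)
})

test_that("the coloc curve peaks at zero offset for a copied channel", {
  set.seed(16)
  # cluster in one corner so the rotated null is far away
  rl <- locs_from_xy(runif(60, 500, 3000), runif(60, 500, 3000))
  curve <- coloc_curve(rl, rl, seq(0, 500, 10), c(40960, 40960))
  expect_equal(curve$F_c[1], 1)  # every reference matched already at t = 0
  expect_true(all(curve$F_r <= 0.05))
  i_T <- match(curve$T_nm, curve$t_grid_nm)
  expect_gte(curve$z[i_T], max(curve$z) - 1 / 60)  # cutoff sits on the plateau
  expect_equal(curve$F_c[i_T], 1)
  expect_true(all(diff(curve$F_c) >= 0))
  expect_true(all(diff(curve$F_r) >= 0))
  expect_equal(curve$z[which.max(curve$z)], max(curve$z))
})

test_that("an unrelated target channel gives a null score (|z| small)", {
  set.seed(17)
  for (s in 1:3) {
    rl <- locs_from_xy(runif(200, 0, 4e4), runif(200, 0, 4e4))
    tl <- locs_from_xy(runif(150, 0, 4e4), runif(150, 0, 4e4))
    curve <- coloc_curve(rl, tl, seq(0, 500, 25), c(40960, 40960))
    se <- sqrt(curve$F_c * (1 - curve$F_c) / 200 +
                 curve$F_r * (1 - curve$F_r) / 200)
    expect_true(all(abs(curve$z) <= 3 * se + 1e-12))
  }
})

test_that("F_c at the grid end is exact for a target subset of the reference", {
  set.seed(18)
  rl <- locs_from_xy(runif(80, 0, 4e4), runif(80, 0, 4e4))
  sub <- as.data.frame(rl)[1:32, ]
  tl <- localization_set(sub, pixel_size_nm = 160)
  curve <- coloc_curve(rl, tl, seq(0, 500, 10), c(40960, 40960))
  expect_equal(curve$F_c[length(curve$F_c)], 32 / 80)
})

test_that("the cutoff is invariant under a common rigid transform", {
  set.seed(19)
  n <- 120
  rx <- runif(n, 5000, 35000); ry <- runif(n, 5000, 35000)
  lab <- runif(n) < 0.6
  tx <- rx[lab] + rnorm(sum(lab), 0, 20)
  ty <- ry[lab] + rnorm(sum(lab), 0, 20)
  rl <- locs_from_xy(rx, ry); tl <- locs_from_xy(tx, ty)
  grid <- seq(0, 500, 10)
  c1 <- coloc_curve(rl, tl, grid, c(40960, 40960))
  rigid <- affine_from_params(shift_nm = c(800, -400), rotation_deg = 3)
  c2 <- coloc_curve(apply_transform(rl, rigid), apply_transform(tl, rigid),
                    grid, c(40960, 40960))
  # specific colocalization is exactly invariant; the rotated-channel null
  # depends on frame position, so the plateau edge (and with it the cutoff)
  # can move along the flat part of the score
  expect_equal(c2$F_c, c1$F_c)
  expect_lte(abs(c2$T_nm - c1$T_nm), 100)
  i1 <- match(c1$T_nm, grid); i2 <- match(c2$T_nm, grid)
  expect_lte(abs(c1$F_c[i1] - c2$F_c[i2]), 0.02)
})

test_that("degree of colocalization is the matched fraction of references", {
  set.seed(20)
  rl <- locs_from_xy(runif(100, 0, 4e4), runif(100, 0, 4e4))
  expect_equal(degree_of_colocalization(rl, rl, 50), 1)
  empty <- localization_set(NULL, pixel_size_nm = 160)
  expect_equal(degree_of_colocalization(rl, empty, 50), 0)
  sub <- localization_set(as.data.frame(rl)[1:40, ], pixel_size_nm = 160)
  expect_equal(degree_of_colocalization(rl, sub, 50), 0.4)
  expect_error(degree_of_colocalization(empty, rl, 50), "undefined")
})

test_that("unspecific density modes count the expected signals", {
  cm <- cell_mask(matrix(1L, 100, 100), 158.11)  # ~250 um^2
  expect_equal(cm$area_um2, 100^2 * 0.15811^2, tolerance = 1e-6)
  empty <- localization_set(NULL, pixel_size_nm = 158.11)
  expect_equal(unspecific_density(empty, cm), 0)
  set.seed(21)
  tl <- locs_from_xy(runif(50, 0, 100 * 158.11), runif(50, 0, 100 * 158.11),
                     pixel_size_nm = 158.11)
  expect_equal(unspecific_density(tl, cm), 50 / cm$area_um2)
  # residual mode: matched targets are not unspecific
  rl <- tl
  expect_equal(unspecific_density(tl, cm, rl, 50, mode = "residual"), 0)
})
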