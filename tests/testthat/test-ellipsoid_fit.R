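test_that("sphere points recover the symmetric quadric", {
  q <- fit_quadric(phantom_sphere_points(50))
  co <- q$coef / q$coef[["a"]]
  expect_equal(unname(co[c("a", "b", "c")]), c(1, 1, 1), tolerance = 1e-8)
  expect_equal(unname(co[c("f", "g", "h", "p", "q", "r")]), rep(0, 6),
               tolerance = 1e-8)
  expect_equal(unname(co[["d"]]), -1, tolerance = 1e-8)
  expect_gt(q$k * q$J - q$I^2, 0)
  expect_lt(attr(q, "rms_residual"), 1e-8)
})

test_that("exact surface points of a rotated, translated ellipsoid are recovered", {
  withr::local_seed(7)
  e0 <- ellipsoid(c(12, -8, 5), c(20, 15, 10), random_rotation())
  pts <- ellipsoid_surface_points(e0, 150)
  fit <- quadric_to_ellipsoid(fit_quadric(pts))
  expect_equal(fit$semi_axes, c(20, 15, 10), tolerance = 1e-9)
  expect_equal(fit$center, c(12, -8, 5), tolerance = 1e-9)
})

test_that("degenerate configurations are rejected", {
  flat <- tibble::tibble(x = runif(12), y = runif(12), z = 0)
  expect_error(fit_quadric(flat), class = "lesionfit3d_error_rank")
  expect_error(fit_quadric(phantom_sphere_points(8)),
               class = "lesionfit3d_error_insufficient_data")
  expect_error(fit_quadric(phantom_sphere_points(50), k = 3),
               class = "lesionfit3d_error_validation")
})

test_that("quadric_to_ellipsoid matches closed forms and rejects non-ellipsoids", {
  sph <- quadric_to_ellipsoid(quadric(c(1, 1, 1, 0, 0, 0, 0, 0, 0, -1)))
  expect_equal(sph$center, c(0, 0, 0))
  expect_equal(sph$semi_axes, c(1, 1, 1))

  ax <- quadric_to_ellipsoid(quadric(c(1, 4, 9, 0, 0, 0, 0, 0, 0, -1)))
  expect_equal(ax$semi_axes, c(1, 0.5, 1 / 3))
  expect_equal(abs(ax$rotation), diag(3), tolerance = 1e-12)

  expect_error(quadric_to_ellipsoid(quadric(c(1, 1, -1, 0, 0, 0, 0, 0, 0, -1))),
               class = "lesionfit3d_error_non_ellipsoid")
})

test_that("fit is equivariant under rigid motions and scaling", {
  withr::local_seed(11)
  base <- ellipsoid(c(0, 0, 0), c(18, 13, 9), diag(3))
  pts0 <- ellipsoid_surface_points(base, 120)
  for (i in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    moved <- tibble::tibble(
      x = R[1, 1] * pts0$x + R[1, 2] * pts0$y + R[1, 3] * pts0$z + t[1],
      y = R[2, 1] * pts0$x + R[2, 2] * pts0$y + R[2, 3] * pts0$z + t[2],
      z = R[3, 1] * pts0$x + R[3, 2] * pts0$y + R[3, 3] * pts0$z + t[3]
    )
    fit <- quadric_to_ellipsoid(fit_quadric(moved))
    expect_equal(fit$semi_axes, c(18, 13, 9), tolerance = 1e-7)
    expect_equal(fit$center, t, tolerance = 1e-7)
  }
  for (s in c(0.1, 2, 37)) {
    fs <- quadric_to_ellipsoid(fit_quadric(pts0 * s))
    expect_equal(fs$semi_axes, s * c(18, 13, 9), tolerance = 1e-9)
  }
})

test_that("every successful fit satisfies the positive constraint with k = 4", {
  withr::local_seed(3)
  for (i in 1:10) {
    ax <- sort(runif(3, 5, 20), decreasing = TRUE)
    e0 <- ellipsoid(rnorm(3, sd = 10), ax, random_rotation())
    q <- fit_quadric(ellipsoid_surface_points(e0, 80))
    expect_equal(4 * q$J - q$I^2, 1, tolerance = 1e-6)
  }
})

test_that("constrained fit agrees with the unconstrained algebraic oracle on exact points", {
  withr::local_seed(19)
  for (i in 1:5) {
    ax <- random_admissible_axes(6, 18)
    e0 <- ellipsoid(rnorm(3, sd = 8), ax, random_rotation())
    pts <- ellipsoid_surface_points(e0, 90)
    fit <- quadric_to_ellipsoid(fit_quadric(pts))
    orc <- oracle_algebraic_fit(pts)
    expect_equal(fit$semi_axes, orc$semi_axes, tolerance = 1e-6)
    expect_equal(fit$center, orc$center, tolerance = 1e-6)
  }
})

test_that("fit_ellipsoid recovers voxelized phantoms on fine grids", {
  ph <- voxelize_ellipsoid(c(10, 10, 10), dx = 1, slice_thickness = 1, slice_gap = 0)
  fit <- fit_ellipsoid(ph$mask)
  expect_equal(fit$semi_axes, rep(10, 3), tolerance = 0.05)

  single <- make_block_mask(7, 7, 5, c(2, 2, 3), c(6, 6, 3))
  expect_error(fit_ellipsoid(single), class = "lesionfit3d_error_insufficient_data")
})

test_that("fit_ellipsoid is deterministic", {
  ph <- voxelize_ellipsoid(c(14, 9, 6), rotation = rotation_from_tilt(35, 70),
                           center_offset = c(0.7, -0.4, 1.1))
  f1 <- fit_ellipsoid(ph$mask)
  f2 <- fit_ellipsoid(ph$mask)
  expect_identical(f1$semi_axes, f2$semi_axes)
  expect_identical(f1$rotation, f2$rotation)
})
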