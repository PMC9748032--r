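test_that("ellipsoid volume and diameter follow the closed forms", {
  expect_equal(ellipsoid_volume(ellipsoid(c(0, 0, 0), c(5, 5, 5))), 0.5236,
               tolerance = 1e-4)
  expect_equal(ellipsoid_volume(ellipsoid(c(0, 0, 0), c(10, 10, 10))), 4.18879,
               tolerance = 1e-5)
  expect_equal(ellipsoid_volume(ellipsoid(c(0, 0, 0), c(9, 6, 4))), 0.904779,
               tolerance = 1e-6)

  expect_equal(ellipsoid_tmd(ellipsoid(c(0, 0, 0), c(8.35, 5, 3))), 1.67)
  expect_equal(ellipsoid_tmd(ellipsoid(c(0, 0, 0), c(7.5, 7.5, 7.5))), 1.5)
  expect_equal(ellipsoid_tmd(ellipsoid(c(0, 0, 0), c(5, 5, 11))), 2.2)

  # pure functions: repeated calls identical
  e <- ellipsoid(c(1, 2, 3), c(9, 6, 4), rotation_from_tilt(20, 30))
  expect_identical(ellipsoid_volume(e), ellipsoid_volume(e))
  expect_identical(ellipsoid_tmd(e), ellipsoid_tmd(e))
})

test_that("planimetric volume is area sum times slice profile", {
  # three slices with areas 20, 30, 25 mm^2 at 1 mm^2 pixels
  occ <- array(FALSE, c(10, 10, 3))
  occ[1:4, 1:5, 1] <- TRUE   # 20
  occ[1:5, 1:6, 2] <- TRUE   # 30
  occ[1:5, 1:5, 3] <- TRUE   # 25
  g6 <- voxel_grid(10, 10, 3, dx = 1, slice_thickness = 3, slice_gap = 3)
  m6 <- lesion_mask(occ, g6)
  expect_equal(planimetric_volume(m6), 0.45)

  g3 <- voxel_grid(10, 10, 3, dx = 1, slice_thickness = 3, slice_gap = 0)
  m3 <- lesion_mask(occ, g3)
  expect_equal(planimetric_volume(m3), planimetric_volume(m6) / 2)

  one <- array(FALSE, c(10, 10, 1)); one[1:10, 1:10, 1] <- TRUE
  g1 <- voxel_grid(10, 10, 1, dx = 1, slice_thickness = 3, slice_gap = 3)
  expect_equal(planimetric_volume(lesion_mask(one, g1)), 0.6)

  # linear in pixel area too
  g2 <- voxel_grid(10, 10, 3, dx = 2, slice_thickness = 3, slice_gap = 3)
  expect_equal(planimetric_volume(lesion_mask(occ, g2)), 4 * 0.45)

  empty <- lesion_mask(array(FALSE, c(2, 2, 1)),
                       voxel_grid(2, 2, 1, dx = 1, slice_thickness = 3))
  expect_error(planimetric_volume(empty), class = "lesionfit3d_error_empty_input")
})

test_that("axial diameter is the Feret diameter of the largest slice", {
  # 3-4-5 triangle: voxels at in-plane mm offsets (0,0) and (3,4)
  occ <- array(FALSE, c(6, 6, 1))
  occ[1, 1, 1] <- TRUE; occ[4, 5, 1] <- TRUE
  g <- voxel_grid(6, 6, 1, dx = 1, slice_thickness = 3, slice_gap = 3)
  expect_equal(axial_max_diameter(lesion_mask(occ, g)), 0.5)

  # rasterized disc r = 5 mm at 0.49 mm pixels vs brute-force oracle
  n <- 31
  roi <- disc_roi(n, 5, 0.49)
  gd <- voxel_grid(n, n, 1, dx = 0.49, slice_thickness = 3, slice_gap = 3)
  md <- stack_rois(list(roi * 1), gd)
  expect_equal(axial_max_diameter(md), oracle_feret_cm(roi, 0.49, 0.49))
  expect_lt(abs(axial_max_diameter(md) - 1.0), 0.49 * sqrt(2) / 10)

  # argmax-area slice rule
  occ2 <- array(FALSE, c(8, 8, 2))
  occ2[1:5, 1:2, 1] <- TRUE          # 10 voxels, widest extent 4 mm
  occ2[3:6, 3:5, 2] <- TRUE          # 12 voxels
  g2 <- voxel_grid(8, 8, 2, dx = 1, slice_thickness = 3, slice_gap = 3)
  d2 <- axial_max_diameter(lesion_mask(occ2, g2))
  expect_equal(d2, oracle_feret_cm(occ2[, , 2], 1, 1))

  # single-voxel slice: degenerate
  occ3 <- array(FALSE, c(4, 4, 1)); occ3[2, 2, 1] <- TRUE
  g3 <- voxel_grid(4, 4, 1, dx = 1, slice_thickness = 3, slice_gap = 3)
  expect_warning(d3 <- axial_max_diameter(lesion_mask(occ3, g3)),
                 class = "lesionfit3d_warning_degenerate_measurement")
  expect_equal(d3, 0)
})

test_that("tilted lesions: 3D diameter exceeds the axial measurement", {
  for (tilt in c(30, 45, 60)) {
    ph <- voxelize_ellipsoid(c(14, 8, 6), rotation = rotation_from_tilt(tilt, 25),
                             center_offset = c(0.9, 0.4, 1.3))
    fit <- fit_ellipsoid(ph$mask)
    expect_gt(ellipsoid_tmd(fit), axial_max_diameter(ph$mask))
  }
})

test_that("measure_lesion reports both methods consistently", {
  ph <- voxelize_ellipsoid(c(12, 9, 7), dx = 1, slice_thickness = 1, slice_gap = 0)
  m <- measure_lesion(ph$mask)
  expect_equal(m$method, c("manual2d", "ellipsoid3d"))
  expect_equal(m$tv_cc[1], planimetric_volume(ph$mask))
  fit <- fit_ellipsoid(ph$mask)
  expect_equal(m$tv_cc[2], ellipsoid_volume(fit))
  expect_equal(m$tmd_cm[2], ellipsoid_tmd(fit))
})
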