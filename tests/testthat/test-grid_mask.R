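test_that("stack_rois concatenates ROIs without resampling", {
  g <- voxel_grid(5, 5, 3, dx = 1, slice_thickness = 3, slice_gap = 3)
  roi <- matrix(0, 5, 5)
  roi[2:3, 2] <- 1
  m <- stack_rois(rep(list(roi), 3), g)
  expect_equal(voxel_count(m), 6L)
  expect_equal(m$occupancy[, , 2], roi > 0)

  g1 <- voxel_grid(3, 3, 1, dx = 1, slice_thickness = 3)
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  expect_equal(voxel_count(stack_rois(list(one), g1)), 1L)

  expect_error(stack_rois(list(), g), class = "lesionfit3d_error_empty_input")
  bad <- list(roi, roi, matrix(0, 4, 5))
  expect_error(stack_rois(bad, g), class = "lesionfit3d_error_dimension")
  expect_error(stack_rois(rep(list(roi), 2), g), class = "lesionfit3d_error_dimension")
})

test_that("interpolation between identical shapes is constant", {
  n <- 25
  roi <- disc_roi(n, r = 5, dx = 1)
  g <- voxel_grid(n, n, 2, dx = 1, slice_thickness = 3, slice_gap = 3)
  m <- stack_rois(list(roi * 1, roi * 1), g)
  fine <- interpolate_z(m)
  expect_equal(fine$grid$slice_thickness, 1)
  expect_equal(fine$grid$slice_gap, 0)
  for (k in seq_len(fine$grid$nz)) {
    expect_equal(fine$occupancy[, , k], roi)
  }
})

test_that("concentric-disc midpoint slice matches the signed-distance oracle", {
  n <- 31
  g <- voxel_grid(n, n, 2, dx = 1, slice_thickness = 3, slice_gap = 3)
  m <- stack_rois(list(disc_roi(n, 5, 1) * 1, disc_roi(n, 3, 1) * 1), g)
  fine <- interpolate_z(m)
  # original slice centres reproduce input ROIs exactly
  z <- grid_z_values(fine)
  expect_equal(fine$occupancy[, , which.min(abs(z - 0))], disc_roi(n, 5, 1))
  expect_equal(fine$occupancy[, , which.min(abs(z - 6))], disc_roi(n, 3, 1))
  # midpoint: a disc of radius 4, allow one in-plane pixel of slack
  mid <- fine$occupancy[, , which.min(abs(z - 3))]
  oracle <- oracle_disc_midslice(5, 3, 0.5, n, 1)
  expect_true(all(mid[!oracle] == FALSE | disc_roi(n, 5, 1)[!oracle]))
  r_mid <- sqrt(sum(mid) / pi)  # effective radius from area
  expect_lt(abs(r_mid - 4), 1)
})

test_that("a single-slice lesion spans one slice profile after interpolation", {
  n <- 15
  g <- voxel_grid(n, n, 1, dx = 1, slice_thickness = 3, slice_gap = 3)
  m <- stack_rois(list(disc_roi(n, 4, 1) * 1), g)
  fine <- interpolate_z(m)
  z <- grid_z_values(fine)
  occ_z <- range(z[apply(fine$occupancy, 3, any)])
  # shape held over the centre +/- (thickness+gap)/2, sampled at 1 mm
  expect_equal(occ_z, c(-3, 3))
})

test_that("interpolate_z is idempotent on 1 mm grids", {
  n <- 19
  occ <- array(FALSE, c(n, n, 9))
  for (k in 2:8) occ[, , k] <- disc_roi(n, 6 - abs(k - 5), 1)
  g <- voxel_grid(n, n, 9, dx = 1, slice_thickness = 1, slice_gap = 0)
  m <- lesion_mask(occ, g)
  fine <- interpolate_z(m)
  z_in <- grid_z_values(m)[apply(occ, 3, any)]
  z_out <- grid_z_values(fine)[apply(fine$occupancy, 3, any)]
  expect_equal(z_out, z_in)
  for (k in 2:8) {
    expect_equal(fine$occupancy[, , which(grid_z_values(fine) == z_in[k - 1])],
                 occ[, , k])
  }
})

test_that("interpolated voxel volume tracks the planimetric volume on a convex phantom", {
  # sphere on the clinical DWI-like grid, generically placed (not slice-tangent)
  ph <- voxelize_ellipsoid(c(11, 11, 11), center_offset = c(0, 0, 1.5))
  expect_gte(sum(apply(ph$mask$occupancy, 3, any)), 3)
  fine <- interpolate_z(ph$mask)
  v_interp <- voxel_count(fine) * fine$grid$dx * fine$grid$dy *
    fine$grid$slice_thickness / 1000
  v_plan <- planimetric_volume(ph$mask)
  expect_lt(abs(v_interp - v_plan) / v_plan, 0.15)
})

test_that("boundary_points returns exactly the exposed voxel centres", {
  m1 <- make_block_mask(3, 3, 3, c(2, 2, 2), c(2, 2, 2))
  bp <- boundary_points(m1)
  expect_equal(nrow(bp), 1L)
  expect_equal(unlist(bp[1, ], use.names = FALSE), c(1, 1, 6))

  m3 <- make_block_mask(5, 5, 5, c(2, 2, 2), c(4, 4, 4))
  expect_equal(nrow(boundary_points(m3)), 26L)

  m5 <- make_block_mask(7, 7, 7, c(2, 2, 2), c(6, 6, 6))
  expect_equal(nrow(boundary_points(m5)), 98L)  # 125 - 27 interior

  expect_error(
    boundary_points(lesion_mask(array(FALSE, c(2, 2, 2)),
                                voxel_grid(2, 2, 2, dx = 1, slice_thickness = 1))),
    class = "lesionfit3d_error_empty_input"
  )
})

test_that("boundary voxels are a subset whose removal shrinks the mask", {
  ph <- voxelize_ellipsoid(c(8, 6, 5), dx = 1, slice_thickness = 1, slice_gap = 0)
  m <- ph$mask
  bp <- boundary_points(m)
  centers <- do.call(rbind, lapply(seq_len(m$grid$nz), function(k) {
    ind <- which(m$occupancy[, , k], arr.ind = TRUE)
    if (nrow(ind) == 0) return(NULL)
    cbind((ind[, 1] - 1) * m$grid$dx + m$grid$origin[1],
          (ind[, 2] - 1) * m$grid$dy + m$grid$origin[2],
          m$grid$origin[3] + (k - 1))
  }))
  key <- function(M) paste(round(M[, 1], 6), round(M[, 2], 6), round(M[, 3], 6))
  expect_true(all(key(as.matrix(bp)) %in% key(centers)))
  expect_lt(nrow(bp), voxel_count(m))
})

test_that("contour_face_points lie half a pixel outside inside centres", {
  n <- 9
  g <- voxel_grid(n, n, 1, dx = 2, slice_thickness = 3, slice_gap = 3)
  roi <- matrix(0, n, n); roi[5, 5] <- 1
  m <- stack_rois(list(roi), g)
  cf <- contour_face_points(m)
  expect_equal(nrow(cf), 4L)
  expect_setequal(round(cf$x - 8, 6), c(-1, 1, 0, 0))
  expect_setequal(round(cf$y - 8, 6), c(0, 0, -1, 1))
})
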