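#' Rotation matrix from tilt and azimuth of the major axis
#'
#' Builds a proper rotation whose first column (the major-axis direction) is
#' tilted `tilt_deg` out of the axial (xy) plane at in-plane azimuth
#' `azimuth_deg`; the remaining axes complete a right-handed frame.
#'
#' @param tilt_deg Angle (degrees) between the major axis and the axial plane.
#' @param azimuth_deg In-plane direction (degrees) of the major axis.
#' @param spin_deg Rotation (degrees) about the major axis.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_tilt <- function(tilt_deg, azimuth_deg = 0, spin_deg = 0) {
  t <- tilt_deg * pi / 180
  a <- azimuth_deg * pi / 180
  s <- spin_deg * pi / 180
  v1 <- c(cos(t) * cos(a), cos(t) * sin(a), sin(t))
  v2 <- c(-sin(a), cos(a), 0)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  R <- cbind(v1, cos(s) * v2 + sin(s) * v3, -sin(s) * v2 + cos(s) * v3)
  dimnames(R) <- NULL
  R
}

default_phantom_grid <- function(semi_axes, rotation, center_offset,
                                 dx, dy, slice_thickness, slice_gap,
                                 margin = 1L, extent_scale = 1) {
  step <- slice_thickness + slice_gap
  # half-extent of the rotated ellipsoid along each world axis
  M <- rotation %*% diag(semi_axes, 3)
  ext <- sqrt(rowSums(M^2)) * extent_scale
  nhx <- ceiling((ext[1] + abs(center_offset[1])) / dx) + margin
  nhy <- ceiling((ext[2] + abs(center_offset[2])) / dy) + margin
  nhz <- ceiling((ext[3] + abs(center_offset[3])) / step) + margin
  voxel_grid(
    2L * nhx + 1L, 2L * nhy + 1L, 2L * nhz + 1L,
    dx = dx, dy = dy, slice_thickness = slice_thickness, slice_gap = slice_gap,
    origin = c(-nhx * dx, -nhy * dy, -nhz * step)
  )
}

#' Voxelize an ellipsoid phantom
#'
#' Rasterizes an ellipsoid onto an MRI-like voxel grid: a voxel is inside iff
#' its centre satisfies the standard-form inequality
#' \eqn{x^2/a^2 + y^2/b^2 + z^2/c^2 \le 1} in the ellipsoid's frame. Returns
#' the mask together with a ground-truth record (analytic volume and maximum
#' diameter) for round-trip validation of the fitting pipeline.
#'
#' When no `grid` is supplied one is constructed to contain the phantom with
#' a one-voxel margin, centred so the phantom centre falls at
#' `center_offset` (mm) from the central voxel — sub-voxel offsets emulate
#' arbitrary lesion positioning relative to the slice stack.
#'
#' @param semi_axes Length-3 positive semi-axes in mm (any order).
#' @param rotation 3x3 rotation matrix (columns = axis directions), e.g. from
#'   [rotation_from_tilt()].
#' @param center_offset Phantom centre (mm) relative to the auto-grid centre;
#'   ignored when `grid` is given (then it is the absolute centre).
#' @param grid Optional explicit [voxel_grid()]; an error is raised if the
#'   phantom extends beyond it.
#' @param dx,dy,slice_thickness,slice_gap Geometry of the auto-constructed
#'   grid; defaults emulate the DWI acquisition (2.6 mm in-plane, 3 mm slices
#'   with 3 mm gap).
#' @return A list with `mask` (a [lesion_mask()]) and `truth` (tibble with
#'   `tv_cc`, `tmd_cm`, semi-axes and voxel count).
#' @export
#' @examples
#' ph <- voxelize_ellipsoid(c(10, 10, 10), dx = 1, slice_thickness = 1,
#'                          slice_gap = 0)
#' ph$truth$tv_cc
voxelize_ellipsoid <- function(semi_axes, rotation = diag(3),
                               center_offset = c(0, 0, 0), grid = NULL,
                               dx = 2.6, dy = dx, slice_thickness = 3,
                               slice_gap = 3) {
  if (!is.numeric(semi_axes) || length(semi_axes) != 3L || any(semi_axes <= 0)) {
    lf_abort("`semi_axes` must be 3 positive numbers (mm).", "validation")
  }
  radial <- make_radial_function(0, seed = NULL)
  voxelize_radial(semi_axes, rotation, center_offset, grid,
                  dx, dy, slice_thickness, slice_gap, radial)
}

#' Voxelize a perturbed (non-ellipsoidal) blob phantom
#'
#' Like [voxelize_ellipsoid()] but the surface radius is modulated by a
#' seeded smooth angular function (a low-order spherical-harmonic-style sum),
#' producing irregular lesions that deliberately violate the ellipsoid model.
#' The ground-truth volume is the voxel-count volume (count times
#' `dx * dy * (slice_thickness + slice_gap)`), since no closed form exists.
#'
#' @inheritParams voxelize_ellipsoid
#' @param perturb_amplitude Peak relative radial perturbation, in `[0, 0.5]`;
#'   0 reproduces [voxelize_ellipsoid()] exactly.
#' @param seed Integer seed making the perturbation reproducible.
#' @return As [voxelize_ellipsoid()]; `truth$tv_cc` is the voxel-count volume.
#' @export
perturb_blob <- function(semi_axes, perturb_amplitude, seed,
                         rotation = diag(3), center_offset = c(0, 0, 0),
                         grid = NULL, dx = 2.6, dy = dx,
                         slice_thickness = 3, slice_gap = 3) {
  if (!is.numeric(perturb_amplitude) || length(perturb_amplitude) != 1L ||
      perturb_amplitude < 0 || perturb_amplitude > 0.5) {
    lf_abort("`perturb_amplitude` must be in [0, 0.5].", "validation")
  }
  radial <- make_radial_function(perturb_amplitude, seed = seed)
  out <- voxelize_radial(semi_axes, rotation, center_offset, grid,
                         dx, dy, slice_thickness, slice_gap, radial,
                         extent_scale = 1 + perturb_amplitude)
  vol_mm3 <- out$truth$n_voxels * dx * dy * (slice_thickness + slice_gap)
  out$truth$tv_cc <- vol_mm3 / 1000
  out$truth$tmd_cm <- NA_real_
  out
}

# seeded smooth function of direction with peak amplitude `amplitude`;
# low-order basis in the direction cosines (degree <= 2 harmonics)
make_radial_function <- function(amplitude, seed) {
  if (amplitude == 0) return(function(U) rep(1, nrow(U)))
  coefs <- withr::with_seed(seed, stats::rnorm(8))
  basis <- function(U) {
    cbind(U[, 1], U[, 2], U[, 3],
          U[, 1] * U[, 2], U[, 2] * U[, 3], U[, 1] * U[, 3],
          U[, 1]^2 - U[, 2]^2, 3 * U[, 3]^2 - 1)
  }
  # normalize the peak over a fixed direction sample so `amplitude` is exact
  dirs <- as.matrix(phantom_sphere_points(400))
  peak <- max(abs(basis(dirs) %*% coefs))
  function(U) 1 + amplitude * drop(basis(U) %*% coefs) / peak
}

voxelize_radial <- function(semi_axes, rotation, center_offset, grid,
                            dx, dy, slice_thickness, slice_gap, radial,
                            extent_scale = 1) {
  if (!is.matrix(rotation) || !all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    lf_abort("`rotation` must be a 3x3 orthonormal matrix.", "validation")
  }
  auto <- is.null(grid)
  if (auto) {
    grid <- default_phantom_grid(semi_axes, rotation, center_offset,
                                 dx, dy, slice_thickness, slice_gap,
                                 extent_scale = extent_scale)
    ctr <- c(0, 0, 0) + center_offset
  } else {
    if (!inherits(grid, "voxel_grid")) lf_abort("`grid` must be a voxel_grid.", "validation")
    ctr <- center_offset
  }

  xs <- grid_x(grid); ys <- grid_y(grid); zs <- grid_z(grid)
  X <- rep(xs, times = grid$ny * grid$nz) - ctr[1]
  Y <- rep(rep(ys, each = grid$nx), times = grid$nz) - ctr[2]
  Z <- rep(zs, each = grid$nx * grid$ny) - ctr[3]
  W <- cbind(X, Y, Z) %*% rotation  # coordinates in the ellipsoid frame
  V <- sweep(W, 2, semi_axes, "/")
  rho <- sqrt(rowSums(V^2))
  inside <- rho <= 1  # placeholder; radial modulation below
  nz_rho <- rho > 1e-12
  f <- rep(1, length(rho))
  f[nz_rho] <- radial(V[nz_rho, , drop = FALSE] / rho[nz_rho])
  inside <- rho <= f
  occ <- array(inside, dim = c(grid$nx, grid$ny, grid$nz))

  if (!any(occ)) {
    lf_abort("Phantom is smaller than one voxel: no voxel centre falls inside.",
             "empty_phantom")
  }
  # truncation check: inside voxels on the volume border mean the grid clips
  # the phantom
  border <- occ
  border[2:(grid$nx - 1), 2:(grid$ny - 1), 2:(grid$nz - 1)] <- FALSE
  if (grid$nx < 3 || grid$ny < 3 || grid$nz < 3 || any(border)) {
    lf_abort("Phantom extends beyond the grid: enlarge the grid.", "truncation")
  }

  truth <- tibble::tibble(
    tv_cc = 4 * pi / 3 * prod(semi_axes) / 1000,
    tmd_cm = 2 * max(semi_axes) / 10,
    a_mm = max(semi_axes),
    b_mm = sort(semi_axes, decreasing = TRUE)[2],
    c_mm = min(semi_axes),
    n_voxels = sum(occ)
  )
  list(mask = lesion_mask(occ, grid), truth = truth)
}

# lognormal parameters matched to a target mean and SD
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Per-score lesion size reference distribution
#'
#' Default generator parameters for [simulate_cohort()]: per-score mean and SD
#' of true tumour volume (cc), taken from the automated ellipsoid-fit columns
#' of the packaged per-score summary fixture (`summary_by_score.csv`).
#'
#' @return Tibble with columns `score`, `tv_mean_cc`, `tv_sd_cc`.
#' @export
default_tv_params <- function() {
  tibble::tibble(
    score = c(3L, 4L, 5L),
    tv_mean_cc = c(0.49, 0.99, 1.05),
    tv_sd_cc = c(0.31, 0.58, 0.78)
  )
}

#' Simulate a measurement cohort
#'
#' Generates a cohort of voxelized lesion phantoms and measures each with both
#' pipelines, so the manual-vs-3D differences in the output arise from the
#' measurement mechanisms themselves (axial slicing, slice gap, tilt) rather
#' than an assumed bias. Per subject: a true tumour volume is drawn from a
#' per-score lognormal (moment-matched to `tv_params`), axis ratios and a
#' major-axis tilt are drawn, the ellipsoid is voxelized on a DWI-like grid at
#' a random sub-voxel position, and the `auto_*` columns are produced by
#' [fit_ellipsoid()] while the `manual_*` columns come from
#' [axial_max_diameter()] and [planimetric_volume()] on the same mask.
#'
#' Lesions whose mask would occupy fewer than two slices are first re-centred
#' midway between slice centres (the multi-slice-visible lesions a radiologist
#' would score) and, failing that, re-drawn in shape (not volume) with
#' progressively more prolate, more tilted geometry — so the configured volume
#' distribution is preserved exactly.
#'
#' @param n_per_score Named vector/list giving the number of subjects per
#'   initial score, e.g. `c("3" = 10, "4" = 18, "5" = 15)`.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param tv_params Tibble with `score`, `tv_mean_cc`, `tv_sd_cc`; defaults to
#'   [default_tv_params()].
#' @param dx,slice_thickness,slice_gap Grid geometry (defaults: DWI-like
#'   2.6 mm in-plane, 3 mm slices, 3 mm gap).
#' @param tilt_range Degrees; major-axis tilt is uniform over this range
#'   (default 0-60) so the axial measurement genuinely misses the major axis
#'   in a known fraction of phantoms.
#' @param axis_ratio_range Range of the uniform draws for b/a and c/b.
#' @return A cohort tibble with columns `subject_id`, `initial_score`,
#'   `manual_tv_cc`, `manual_tmd_cm`, `auto_tv_cc`, `auto_tmd_cm`,
#'   `rescored_score` (NA), plus ground-truth columns `true_tv_cc`,
#'   `true_tmd_cm` and `tilt_deg`.
#' @export
#' @examples
#' co <- simulate_cohort(c("3" = 2, "4" = 2, "5" = 2), seed = 1)
#' nrow(co)
simulate_cohort <- function(n_per_score, seed, tv_params = default_tv_params(),
                            dx = 2.6, slice_thickness = 3, slice_gap = 3,
                            tilt_range = c(0, 60),
                            axis_ratio_range = c(0.6, 0.9)) {
  ns <- unlist(n_per_score)
  if (is.null(names(ns)) || !all(names(ns) %in% c("3", "4", "5")) ||
      any(ns < 1) || any(ns != round(ns))) {
    lf_abort("`n_per_score` must be named with scores 3/4/5 and positive whole counts.",
             "validation")
  }
  step <- slice_thickness + slice_gap
  rows <- withr::with_seed(seed, {
    purrr::map(names(ns), function(sc) {
      par <- tv_params[tv_params$score == as.integer(sc), ]
      if (nrow(par) != 1L) {
        lf_abort(sprintf("No tv_params row for score %s.", sc), "validation")
      }
      lp <- lognormal_params(par$tv_mean_cc, par$tv_sd_cc)
      purrr::map(seq_len(ns[[sc]]), function(i) {
        # volumes too small to span two slices even fully tilted are below
        # the resolvability of the slice stack; the simulated population is
        # multi-slice-visible lesions, so such rare tail draws are re-drawn
        geom <- NULL
        for (attempt in 1:20) {
          tv_true <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
          geom <- tryCatch(
            draw_geometry(tv_true, tilt_range, axis_ratio_range,
                          dx, slice_thickness, slice_gap),
            lesionfit3d_error_validation = function(e) NULL
          )
          if (!is.null(geom)) break
        }
        if (is.null(geom)) {
          lf_abort("Could not generate a resolvable lesion for this score.",
                   "validation")
        }
        mask <- geom$mask
        fit <- geom$fit
        tibble::tibble(
          subject_id = sprintf("S%s_%03d", sc, i),
          initial_score = as.integer(sc),
          manual_tv_cc = planimetric_volume(mask),
          manual_tmd_cm = suppressWarnings(axial_max_diameter(mask)),
          auto_tv_cc = ellipsoid_volume(fit),
          auto_tmd_cm = ellipsoid_tmd(fit),
          rescored_score = NA_integer_,
          true_tv_cc = tv_true,
          true_tmd_cm = 2 * geom$semi_axes[1] / 10,
          tilt_deg = geom$tilt_deg
        )
      })
    })
  })
  dplyr::bind_rows(rows)
}

# draw axis ratios + tilt for a fixed true volume; re-centre then re-draw
# shape until the voxelized mask spans >= 2 slices AND supports a
# non-degenerate ellipsoid fit (tiny two-slice masks can be rank-deficient)
draw_geometry <- function(tv_cc, tilt_range, axis_ratio_range,
                          dx, slice_thickness, slice_gap, max_tries = 8L) {
  step <- slice_thickness + slice_gap
  for (try in seq_len(max_tries)) {
    if (try == 1) {
      rb <- stats::runif(1, axis_ratio_range[1], axis_ratio_range[2])
      rc <- stats::runif(1, axis_ratio_range[1], axis_ratio_range[2])
      tilt <- stats::runif(1, tilt_range[1], tilt_range[2])
    } else {
      # later tries: progressively more prolate, more tilted shapes that
      # span more slices (the lesions a radiologist would call multi-slice)
      rb <- axis_ratio_range[1]
      rc <- axis_ratio_range[1]
      tilt <- max(tilt_range[1], tilt_range[2] * min(try - 1, max_tries - 1) / (max_tries - 1))
    }
    az <- stats::runif(1, 0, 360)
    a <- (3000 * tv_cc / (4 * pi * rb^2 * rc))^(1 / 3)
    semi <- c(a, a * rb, a * rb * rc)
    R <- rotation_from_tilt(tilt, az)
    offs <- list(
      c(stats::runif(1, -dx / 2, dx / 2), stats::runif(1, -dx / 2, dx / 2),
        stats::runif(1, -step / 2, step / 2)),
      NULL
    )
    offs[[2]] <- c(offs[[1]][1], offs[[1]][2], step / 2)  # re-centre midway
    for (off in offs) {
      m <- try_voxelize(semi, R, off, dx, slice_thickness, slice_gap)
      if (is.null(m)) next
      fit <- tryCatch(fit_ellipsoid(m), lesionfit3d_error = function(e) NULL)
      if (is.null(fit)) next
      return(list(mask = m, fit = fit, semi_axes = semi, tilt_deg = tilt))
    }
  }
  lf_abort(sprintf(
    "Could not voxelize a fittable >= 2-slice lesion of %.3f cc on this grid.",
    tv_cc
  ), "validation")
}

try_voxelize <- function(semi, R, off, dx, slice_thickness, slice_gap) {
  out <- tryCatch(
    voxelize_ellipsoid(semi, rotation = R, center_offset = off, dx = dx,
                       slice_thickness = slice_thickness, slice_gap = slice_gap),
    lesionfit3d_error_empty_phantom = function(e) NULL
  )
  if (is.null(out)) return(NULL)
  if (sum(apply(out$mask$occupancy, 3, any)) < 2L) return(NULL)
  out$mask
}
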