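#' Voxel-grid geometry of an MRI mask volume
#'
#' Describes the geometry a binary lesion mask lives on: in-plane spacing,
#' slice thickness, inter-slice gap and physical origin. Consecutive slice
#' centres are separated by `slice_thickness + slice_gap` (6 mm at the
#' clinical defaults of 3 mm thickness plus 3 mm gap), consistent with the
#' planimetric slice-profile factor. The centre of voxel `(i, j, k)`
#' (0-based) sits at `origin + (i * dx, j * dy, k * (slice_thickness +
#' slice_gap))`, all in millimetres.
#'
#' @param nx,ny,nz Positive integer voxel counts along x, y and z.
#' @param dx,dy In-plane voxel spacing in mm (`dy` defaults to `dx`).
#' @param slice_thickness Slice thickness in mm.
#' @param slice_gap Gap between slices in mm (default 0). For data whose
#'   header z-spacing already includes the gap, set `slice_gap = 0` and put
#'   the full centre spacing in `slice_thickness`.
#' @param origin Physical coordinate (mm) of the centre of voxel (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(112, 112, 7, dx = 2.6, slice_thickness = 3, slice_gap = 3)
voxel_grid <- function(nx, ny, nz, dx, dy = dx, slice_thickness,
                       slice_gap = 0, origin = c(0, 0, 0)) {
  for (nm in c("nx", "ny", "nz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      lf_abort(sprintf("`%s` must be a positive whole number.", nm), "validation")
    }
  }
  check_scalar_positive(dx, "dx")
  check_scalar_positive(dy, "dy")
  check_scalar_positive(slice_thickness, "slice_thickness")
  if (!is.numeric(slice_gap) || length(slice_gap) != 1L || slice_gap < 0) {
    lf_abort("`slice_gap` must be a single non-negative number.", "validation")
  }
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin))) {
    lf_abort("`origin` must be a finite length-3 numeric vector.", "validation")
  }
  structure(
    list(
      nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
      dx = dx, dy = dy,
      slice_thickness = slice_thickness, slice_gap = slice_gap,
      origin = as.numeric(origin)
    ),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, %.3g x %.3g mm in-plane, slices %g mm (+%g mm gap)\n",
    x$nx, x$ny, x$nz, x$dx, x$dy, x$slice_thickness, x$slice_gap
  ))
  invisible(x)
}

# Centre-to-centre spacing of consecutive slices (mm).
slice_step <- function(grid) grid$slice_thickness + grid$slice_gap

grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy
grid_z <- function(grid) grid$origin[3] + (seq_len(grid$nz) - 1) * slice_step(grid)

#' Binary lesion mask on a voxel grid
#'
#' The unit every measurement consumes: a logical occupancy array paired with
#' its [voxel_grid()] geometry.
#'
#' @param occupancy Logical (or 0/1 numeric) array with dimensions
#'   `(nx, ny, nz)` of `grid`.
#' @param grid A [voxel_grid()].
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(occupancy, grid) {
  if (!inherits(grid, "voxel_grid")) {
    lf_abort("`grid` must be a voxel_grid.", "validation")
  }
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L) {
    lf_abort("`occupancy` must be a 3-dimensional array.", "dimension")
  }
  if (!identical(dim(occupancy), c(grid$nx, grid$ny, grid$nz))) {
    lf_abort(
      sprintf(
        "occupancy dimensions (%s) do not match grid (%d, %d, %d).",
        paste(dim(occupancy), collapse = ", "), grid$nx, grid$ny, grid$nz
      ),
      "dimension"
    )
  }
  if (is.numeric(occupancy)) {
    if (!all(occupancy %in% c(0, 1))) {
      lf_abort("Numeric occupancy must contain only 0 and 1.", "validation")
    }
    occupancy <- array(occupancy > 0, dim = dim(occupancy))
  }
  if (!is.logical(occupancy)) {
    lf_abort("`occupancy` must be logical or 0/1 numeric.", "validation")
  }
  if (anyNA(occupancy)) lf_abort("occupancy contains missing values.", "validation")
  structure(list(grid = grid, occupancy = occupancy), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask> %d inside voxels on %d x %d x %d grid (%d occupied slices)\n",
    sum(x$occupancy), x$grid$nx, x$grid$ny, x$grid$nz,
    sum(apply(x$occupancy, 3, any))
  ))
  invisible(x)
}

#' Number of inside voxels of a mask
#' @param mask A [lesion_mask()].
#' @return Integer count of inside voxels.
#' @export
voxel_count <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$occupancy)
}

check_nonempty <- function(mask, what = "operation") {
  if (!inherits(mask, "lesion_mask")) {
    lf_abort("Input must be a lesion_mask.", "validation")
  }
  if (voxel_count(mask) == 0L) {
    lf_abort(sprintf("Mask is empty: %s requires at least one inside voxel.", what),
             "empty_input")
  }
  invisible(mask)
}

#' Stack per-slice 2D ROIs into a 3D lesion mask
#'
#' Concatenates manually segmented per-slice regions of interest into a single
#' 3D binary volume on the given grid; no resampling is performed, slice `k`
#' of the result equals input ROI `k`.
#'
#' @param slices List of `nz` binary matrices, each `nx` by `ny`.
#' @param grid A [voxel_grid()] whose `nz` equals `length(slices)`.
#' @return A [lesion_mask()].
#' @export
#' @examples
#' g <- voxel_grid(5, 5, 3, dx = 1, slice_thickness = 3, slice_gap = 3)
#' roi <- matrix(0, 5, 5); roi[2:3, 2] <- 1
#' voxel_count(stack_rois(rep(list(roi), 3), g))
stack_rois <- function(slices, grid) {
  if (!inherits(grid, "voxel_grid")) lf_abort("`grid` must be a voxel_grid.", "validation")
  if (!is.list(slices) || length(slices) == 0L) {
    lf_abort("`slices` must be a non-empty list of per-slice ROI matrices.", "empty_input")
  }
  if (length(slices) != grid$nz) {
    lf_abort(sprintf("Got %d slices for a grid with nz = %d.", length(slices), grid$nz),
             "dimension")
  }
  ok <- vapply(slices, function(s) is.matrix(s) && all(dim(s) == c(grid$nx, grid$ny)),
               logical(1))
  if (!all(ok)) {
    lf_abort(sprintf("Slice %d does not match the grid's (nx, ny) = (%d, %d).",
                     which(!ok)[1], grid$nx, grid$ny), "dimension")
  }
  occ <- array(FALSE, dim = c(grid$nx, grid$ny, grid$nz))
  for (k in seq_along(slices)) occ[, , k] <- slices[[k]] > 0
  lesion_mask(occ, grid)
}

# Signed Euclidean distance (mm) of every pixel of a window to the ROI
# contour: negative inside, positive outside, zero on contour pixels.
# Exact distance to the set of contour pixel centres (inside pixels with a
# 4-connected outside or out-of-window neighbour); handles anisotropic dx/dy.
signed_distance_2d <- function(inside, dx, dy, big = 1e6) {
  ni <- nrow(inside); nj <- ncol(inside)
  if (!any(inside)) return(matrix(big, ni, nj))
  pad <- matrix(FALSE, ni + 2, nj + 2)
  pad[2:(ni + 1), 2:(nj + 1)] <- inside
  core <- pad[2:(ni + 1), 2:(nj + 1)]
  contour <- core & !(pad[1:ni, 2:(nj + 1)] & pad[3:(ni + 2), 2:(nj + 1)] &
                        pad[2:(ni + 1), 1:nj] & pad[2:(ni + 1), 3:(nj + 2)])
  cw <- which(contour, arr.ind = TRUE)
  px <- rep(seq_len(ni), times = nj) * dx
  py <- rep(seq_len(nj), each = ni) * dy
  # min squared distance to contour centres, vectorized over contour points
  d2 <- matrix(Inf, ni, nj)
  cx <- cw[, 1] * dx; cy <- cw[, 2] * dy
  for (m in seq_len(nrow(cw))) {
    d2 <- pmin(d2, matrix((px - cx[m])^2 + (py - cy[m])^2, ni, nj))
  }
  d <- sqrt(d2)
  d[inside] <- -d[inside]
  d
}

#' Shape-based interpolation of a mask to fine slices
#'
#' Resamples a mask along z to `target_spacing` (1 mm by default) so the
#' stacked clinical slices (typically 3 mm thick with a 3 mm gap) become a
#' contiguous fine-sliced volume. Interpolation is shape-based: each original
#' slice is converted to a 2D signed Euclidean distance map (negative inside),
#' the signed distance is interpolated linearly along z between consecutive
#' slice centres, and a resampled voxel is inside where the interpolated value
#' is `<= 0`. Original slice centres therefore reproduce the original ROIs
#' exactly, and the cross-section varies continuously in between, avoiding the
#' stair-step surfaces that bias a subsequent ellipsoid fit.
#'
#' Beyond the first and last occupied slice the end slice's shape is extended
#' outward by `end_extension` mm (default half the slice profile,
#' `(slice_thickness + slice_gap) / 2`, i.e. 3 mm at clinical defaults), so a
#' lesion's z-extent reflects the tissue slab each slice represents — the same
#' convention the planimetric volume uses when it multiplies per-slice areas
#' by the full slice profile.
#'
#' @param mask A non-empty [lesion_mask()].
#' @param target_spacing Output slice centre spacing in mm; must be positive
#'   and no larger than the input slice centre spacing.
#' @param end_extension How far (mm) to extend the first/last occupied slice's
#'   shape beyond its centre. Default `(slice_thickness + slice_gap) / 2`.
#' @return A [lesion_mask()] on a grid with slice thickness `target_spacing`
#'   and zero gap; in-plane geometry unchanged.
#' @export
#' @examples
#' g <- voxel_grid(21, 21, 3, dx = 1, slice_thickness = 3, slice_gap = 3)
#' occ <- array(FALSE, c(21, 21, 3))
#' occ[8:14, 8:14, 1:3] <- TRUE  # constant square column
#' fine <- interpolate_z(lesion_mask(occ, g))
#' fine$grid$nz
interpolate_z <- function(mask, target_spacing = 1, end_extension = NULL) {
  check_nonempty(mask, "interpolate_z")
  grid <- mask$grid
  step <- slice_step(grid)
  check_scalar_positive(target_spacing, "target_spacing")
  if (target_spacing > step + 1e-9) {
    lf_abort("`target_spacing` must not exceed the input slice centre spacing.",
             "validation")
  }
  end_extension <- end_extension %||% (step / 2)
  if (!is.numeric(end_extension) || length(end_extension) != 1L || end_extension < 0) {
    lf_abort("`end_extension` must be a single non-negative number.", "validation")
  }

  occ <- mask$occupancy
  occ_slice <- apply(occ, 3, any)
  k0 <- which(occ_slice)[1]
  k1 <- rev(which(occ_slice))[1]

  # interpolated shapes live inside the union of adjacent slice shapes, so a
  # padded bounding window of the occupied region suffices for the distance maps
  idx <- which(occ, arr.ind = TRUE)
  i0 <- max(1L, min(idx[, 1]) - 1L); i1 <- min(grid$nx, max(idx[, 1]) + 1L)
  j0 <- max(1L, min(idx[, 2]) - 1L); j1 <- min(grid$ny, max(idx[, 2]) + 1L)

  big <- 1e6
  sd_maps <- lapply(k0:k1, function(k) {
    signed_distance_2d(occ[i0:i1, j0:j1, k, drop = TRUE], grid$dx, grid$dy, big = big)
  })

  n_ext <- floor(end_extension / target_spacing + 1e-9)
  span <- (k1 - k0) * step
  rel <- seq(-n_ext, round(span / target_spacing + 1e-9) + n_ext) * target_spacing
  # guard: span may not be a multiple of target_spacing; build rel explicitly
  if (abs(span / target_spacing - round(span / target_spacing)) > 1e-9) {
    inner <- seq(0, span, by = target_spacing)
    rel <- c(rev(inner[1] - seq_len(n_ext) * target_spacing), inner,
             inner[length(inner)] + seq_len(n_ext) * target_spacing)
  }

  nz_out <- length(rel)
  occ_out <- array(FALSE, dim = c(grid$nx, grid$ny, nz_out))
  n_seg <- k1 - k0
  for (m in seq_len(nz_out)) {
    t <- rel[m] / step
    t <- min(max(t, 0), n_seg)
    lo <- min(floor(t + 1e-9), max(n_seg - 1, 0))
    w <- t - lo
    sd <- if (n_seg == 0 || w <= 1e-9) {
      sd_maps[[lo + 1]]
    } else if (w >= 1 - 1e-9) {
      sd_maps[[lo + 2]]
    } else {
      (1 - w) * sd_maps[[lo + 1]] + w * sd_maps[[lo + 2]]
    }
    win <- sd <= 0
    if (any(win)) {
      full <- matrix(FALSE, grid$nx, grid$ny)
      full[i0:i1, j0:j1] <- win
      occ_out[, , m] <- full
    }
  }

  out_grid <- voxel_grid(
    grid$nx, grid$ny, nz_out, dx = grid$dx, dy = grid$dy,
    slice_thickness = target_spacing, slice_gap = 0,
    origin = c(grid$origin[1], grid$origin[2],
               grid$origin[3] + (k0 - 1) * step + rel[1])
  )
  lesion_mask(occ_out, out_grid)
}

#' Physical coordinates of boundary voxel centres
#'
#' Returns the centres (mm) of all inside voxels that touch the outside: at
#' least one 6-connected neighbour is outside the mask or outside the volume.
#' 6-connectivity gives a conservative surface extraction.
#'
#' @param mask A non-empty [lesion_mask()].
#' @return A tibble with columns `x`, `y`, `z` (mm), one row per boundary voxel.
#' @export
boundary_points <- function(mask) {
  check_nonempty(mask, "boundary_points")
  bnd <- boundary_voxels(mask$occupancy)
  voxel_tibble(which(bnd, arr.ind = TRUE), mask$grid)
}

# logical array of inside voxels with a 6-connected outside/out-of-volume neighbour
boundary_voxels <- function(occ) {
  d <- dim(occ)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  interior <- core &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  occ & !interior
}

voxel_tibble <- function(ind, grid) {
  tibble::tibble(
    x = grid$origin[1] + (ind[, 1] - 1) * grid$dx,
    y = grid$origin[2] + (ind[, 2] - 1) * grid$dy,
    z = grid$origin[3] + (ind[, 3] - 1) * slice_step(grid)
  )
}

#' Sub-pixel contour points of each occupied slice
#'
#' For every occupied slice, emits one point per exposed in-plane pixel face
#' (the midpoint between an inside pixel centre and its 4-connected outside
#' neighbour), at the slice's z position. Face midpoints straddle the true
#' contour symmetrically, so they carry no half-pixel inward bias. These are
#' the measured cross-section samples [fit_ellipsoid()] fits.
#'
#' @param mask A non-empty [lesion_mask()].
#' @return A tibble with columns `x`, `y`, `z` (mm) and `slice` (1-based index).
#' @export
contour_face_points <- function(mask) {
  check_nonempty(mask, "contour_face_points")
  grid <- mask$grid
  zs <- grid_z(grid)
  occk <- which(apply(mask$occupancy, 3, any))
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  half <- c(grid$dx / 2, grid$dy / 2)
  out <- lapply(occk, function(k) {
    sl <- mask$occupancy[, , k, drop = TRUE]
    ni <- nrow(sl); nj <- ncol(sl)
    pad <- matrix(FALSE, ni + 2, nj + 2)
    pad[2:(ni + 1), 2:(nj + 1)] <- sl
    pts <- lapply(shifts, function(s) {
      nb <- pad[(2:(ni + 1)) + s[1], (2:(nj + 1)) + s[2]]
      exposed <- sl & !nb
      if (!any(exposed)) return(NULL)
      ind <- which(exposed, arr.ind = TRUE)
      tibble::tibble(
        x = grid$origin[1] + (ind[, 1] - 1) * grid$dx + s[1] * half[1],
        y = grid$origin[2] + (ind[, 2] - 1) * grid$dy + s[2] * half[2],
        z = zs[k],
        slice = k
      )
    })
    dplyr::bind_rows(pts)
  })
  dplyr::bind_rows(out)
}

#' Surface sample points on boundary voxel faces
#'
#' Like [boundary_points()], but emits one point per exposed voxel face,
#' placed at the face centre (half a voxel beyond the boundary voxel centre in
#' the exposed direction). Face midpoints straddle the true surface
#' symmetrically, so a least-squares surface fit through them carries no
#' half-voxel inward bias — unlike boundary voxel centres, which sit up to one
#' voxel inside the surface. Used by [fit_ellipsoid()].
#'
#' @param mask A non-empty [lesion_mask()].
#' @return A tibble with columns `x`, `y`, `z` (mm), one row per exposed face.
#' @export
surface_points <- function(mask) {
  check_nonempty(mask, "surface_points")
  occ <- mask$occupancy
  grid <- mask$grid
  d <- dim(occ)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  shifts <- list(
    c(-1L, 0L, 0L), c(1L, 0L, 0L),
    c(0L, -1L, 0L), c(0L, 1L, 0L),
    c(0L, 0L, -1L), c(0L, 0L, 1L)
  )
  half <- c(grid$dx / 2, grid$dy / 2, slice_step(grid) / 2)
  pts <- lapply(shifts, function(s) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2], (2:(d[3] + 1)) + s[3],
              drop = FALSE]
    dim(nb) <- d
    exposed <- occ & !nb
    if (!any(exposed)) return(NULL)
    p <- voxel_tibble(which(exposed, arr.ind = TRUE), grid)
    p$x <- p$x + s[1] * half[1]
    p$y <- p$y + s[2] * half[2]
    p$z <- p$z + s[3] * half[3]
    p
  })
  dplyr::bind_rows(pts)
}
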