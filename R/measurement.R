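#' Ellipsoid tumour volume (cc)
#'
#' Volume of an ellipsoid with principal semi-axes \eqn{a, b, c}:
#' \eqn{V = \frac{4\pi}{3} a b c}, converted from cubic millimetres to cc.
#'
#' @param e An [ellipsoid()] with semi-axes in mm.
#' @return Tumour volume in cc (ml).
#' @export
#' @examples
#' ellipsoid_volume(ellipsoid(c(0, 0, 0), c(5, 5, 5)))  # 0.5236 cc
ellipsoid_volume <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  4 * pi / 3 * prod(e$semi_axes) / 1000
}

#' Ellipsoid tumour maximum diameter (cm)
#'
#' The tumour maximum diameter is the full major axis of the best-fit
#' ellipsoid, `2 * max(a, b, c)`, which may point in any 3D direction — not
#' necessarily in the axial plane the radiologist measures on.
#'
#' @param e An [ellipsoid()] with semi-axes in mm.
#' @return Maximum diameter in cm.
#' @export
#' @examples
#' ellipsoid_tmd(ellipsoid(c(0, 0, 0), c(8.35, 5, 3)))  # 1.67 cm
ellipsoid_tmd <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  2 * max(e$semi_axes) / 10
}

#' Planimetric tumour volume (cc)
#'
#' The radiologist-style volume: the sum of lesion areas over all slices
#' multiplied by the slice-profile factor (slice thickness plus inter-slice
#' gap, 6 mm at clinical defaults). Must be computed on the original
#' (non-interpolated) grid — the slice profile already accounts for the gap.
#'
#' @param mask A non-empty [lesion_mask()] on the acquisition grid.
#' @return Volume in cc.
#' @export
planimetric_volume <- function(mask) {
  check_nonempty(mask, "planimetric_volume")
  grid <- mask$grid
  area_mm2 <- sum(mask$occupancy) * grid$dx * grid$dy
  area_mm2 * slice_step(grid) / 1000
}

#' Axial maximum diameter (cm)
#'
#' The radiologist-style 2D diameter: on the axial slice with the largest ROI
#' area (ties broken by the lower slice index), the maximum pairwise distance
#' between inside-voxel centres — the 2D Feret diameter. Computed exactly over
#' the convex hull of the slice's voxel centres; sub-pixel edge extent is
#' ignored.
#'
#' @param mask A non-empty [lesion_mask()].
#' @return Diameter in cm. A single-voxel largest slice returns 0 with a
#'   degenerate-measurement warning.
#' @export
axial_max_diameter <- function(mask) {
  check_nonempty(mask, "axial_max_diameter")
  grid <- mask$grid
  areas <- apply(mask$occupancy, 3, sum)
  k <- which.max(areas)  # which.max takes the first maximum: lower slice wins ties
  sl <- mask$occupancy[, , k, drop = TRUE]
  ind <- which(sl, arr.ind = TRUE)
  if (nrow(ind) == 1L) {
    lf_warn("Largest slice contains a single voxel: axial diameter is degenerate (0).",
            "degenerate_measurement")
    return(0)
  }
  pts <- cbind((ind[, 1] - 1) * grid$dx, (ind[, 2] - 1) * grid$dy)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  sqrt(max(d2)) / 10
}

#' Measure a lesion with both methods
#'
#' Convenience wrapper returning the radiologist-style 2D measurements
#' (planimetric volume, axial Feret diameter) and the automated 3D
#' ellipsoid-fit measurements for one mask, as a tidy tibble.
#'
#' @param mask A [lesion_mask()] on the acquisition grid.
#' @param k Constraint parameter for [fit_ellipsoid()].
#' @return A tibble with columns `method` (`"manual2d"`, `"ellipsoid3d"`),
#'   `tmd_cm` and `tv_cc`.
#' @export
measure_lesion <- function(mask, k = 4) {
  check_nonempty(mask, "measure_lesion")
  fit <- fit_ellipsoid(mask, k = k)
  tibble::tibble(
    method = c("manual2d", "ellipsoid3d"),
    tmd_cm = c(axial_max_diameter(mask), ellipsoid_tmd(fit)),
    tv_cc = c(planimetric_volume(mask), ellipsoid_volume(fit))
  )
}
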