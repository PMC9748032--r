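#' Quadric surface coefficients
#'
#' A general second-degree surface
#' \deqn{a x^2 + b y^2 + c z^2 + 2 f y z + 2 g x z + 2 h x y
#'       + 2 p x + 2 q y + 2 r z + d = 0}
#' together with the rotation invariants of its quadratic form,
#' \eqn{I = a + b + c} and \eqn{J = ab + bc + ac - f^2 - g^2 - h^2}, and the
#' ellipsoid-specificity parameter `k`. Coefficient vectors returned by
#' [fit_quadric()] are normalized so that \eqn{kJ - I^2 = 1}; the constraint
#' value being positive is what guarantees the surface is an ellipsoid (for
#' `k = 4`, any ellipsoid with comparable semi-axis lengths).
#'
#' @param coef Named or unnamed numeric vector of length 10 in the order
#'   `(a, b, c, f, g, h, p, q, r, d)`.
#' @param k Constraint parameter (default 4).
#' @return An object of class `quadric` with elements `coef`, `k`, `I`, `J`.
#' @export
quadric <- function(coef, k = 4) {
  if (!is.numeric(coef) || length(coef) != 10L || !all(is.finite(coef))) {
    lf_abort("`coef` must be 10 finite numbers (a, b, c, f, g, h, p, q, r, d).",
             "validation")
  }
  if (all(coef == 0)) lf_abort("Coefficient vector must be nonzero.", "validation")
  coef <- as.numeric(coef)
  names(coef) <- c("a", "b", "c", "f", "g", "h", "p", "q", "r", "d")
  I <- coef["a"] + coef["b"] + coef["c"]
  J <- coef["a"] * coef["b"] + coef["b"] * coef["c"] + coef["a"] * coef["c"] -
    coef["f"]^2 - coef["g"]^2 - coef["h"]^2
  structure(
    list(coef = coef, k = k, I = unname(I), J = unname(J)),
    class = "quadric"
  )
}

#' @export
print.quadric <- function(x, ...) {
  cat("<quadric> kJ - I^2 =", x$k * x$J - x$I^2, "\n")
  print(signif(x$coef, 6))
  invisible(x)
}

# symmetric 3x3 matrix of the quadratic form
quadric_matrix <- function(q) {
  co <- q$coef
  matrix(c(co["a"], co["h"], co["g"],
           co["h"], co["b"], co["f"],
           co["g"], co["f"], co["c"]), 3, 3)
}

#' Ellipsoid in geometric form
#'
#' Centre, ordered principal semi-axes and orientation of an ellipsoid. In the
#' ellipsoid's own frame the surface is the standard form
#' \eqn{x^2/a^2 + y^2/b^2 + z^2/c^2 = 1} with principal semi-axes
#' \eqn{a \ge b \ge c > 0}; `rotation` is a proper orthonormal matrix whose
#' columns are the axis directions in world coordinates.
#'
#' @param center Numeric length-3 centre (mm).
#' @param semi_axes Numeric length-3 semi-axes (mm); stored sorted descending.
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1) whose
#'   columns correspond to `semi_axes`.
#' @return An object of class `ellipsoid`.
#' @export
#' @examples
#' e <- ellipsoid(c(0, 0, 0), c(10, 7, 5), diag(3))
#' ellipsoid_tmd(e)
ellipsoid <- function(center, semi_axes, rotation = diag(3)) {
  if (!is.numeric(center) || length(center) != 3L || !all(is.finite(center))) {
    lf_abort("`center` must be 3 finite numbers.", "validation")
  }
  if (!is.numeric(semi_axes) || length(semi_axes) != 3L || any(semi_axes <= 0)) {
    lf_abort("`semi_axes` must be 3 positive numbers.", "non_ellipsoid")
  }
  if (!is.matrix(rotation) || !all(dim(rotation) == c(3, 3))) {
    lf_abort("`rotation` must be a 3x3 matrix.", "validation")
  }
  ord <- order(semi_axes, decreasing = TRUE)
  semi_axes <- semi_axes[ord]
  rotation <- rotation[, ord, drop = FALSE]
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    lf_abort("`rotation` must be orthonormal to within 1e-9.", "validation")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    lf_abort("`rotation` must have determinant +1 to within 1e-9.", "validation")
  }
  structure(
    list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
         rotation = rotation),
    class = "ellipsoid"
  )
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid> semi-axes (%.4g, %.4g, %.4g) mm, centre (%.4g, %.4g, %.4g) mm\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
    x$center[1], x$center[2], x$center[3]
  ))
  invisible(x)
}

#' Constraint value of a standard-form ellipsoid
#'
#' Evaluates \eqn{kJ - I^2} for the quadric of an axis-aligned ellipsoid with
#' the given semi-axes (the value is rotation- and translation-invariant, and
#' its *sign* is also invariant under coordinate scaling). The constrained
#' fit can only represent quadrics with a positive value: with `k = 4` this
#' is the "comparable semi-axes" applicability domain of the method. An
#' ellipsoid with a negative value (strongly unequal axes, e.g. 18:12:7)
#' cannot be recovered exactly by the `k = 4` fit — the fit returns the
#' closest constraint-admissible ellipsoid instead.
#'
#' @param semi_axes Length-3 positive semi-axes.
#' @param k Constraint parameter (default 4).
#' @return The (scale-dependent) value of `k * J - I^2`; only its sign is
#'   geometry-invariant.
#' @export
#' @examples
#' ellipsoid_constraint_value(c(20, 15, 10)) > 0  # admissible
#' ellipsoid_constraint_value(c(20, 10, 5)) > 0   # not exactly representable
ellipsoid_constraint_value <- function(semi_axes, k = 4) {
  if (!is.numeric(semi_axes) || length(semi_axes) != 3L || any(semi_axes <= 0)) {
    lf_abort("`semi_axes` must be 3 positive numbers.", "validation")
  }
  p <- 1 / semi_axes^2
  I <- sum(p)
  J <- p[1] * p[2] + p[2] * p[3] + p[1] * p[3]
  k * J - I^2
}

# constraint matrix of kJ - I^2 as a quadratic form on (a, b, c, f, g, h):
# -a^2 - b^2 - c^2 + (k - 2)(ab + ac + bc) - k(f^2 + g^2 + h^2)
constraint_block <- function(k) {
  C1 <- matrix(0, 6, 6)
  C1[1:3, 1:3] <- (k - 2) / 2
  diag(C1) <- c(-1, -1, -1, -k, -k, -k)
  C1
}

#' Ellipsoid-specific least-squares quadric fit
#'
#' Fits a quadric surface to 3D points by minimizing the algebraic residual
#' `||D u||^2` over the 10 coefficients `u`, subject to the ellipsoid-specific
#' normalization \eqn{kJ - I^2 = 1} where `I` and `J` are the invariants of
#' the quadratic form. With `k = 4` every solution satisfying the constraint
#' with a positive value is an ellipsoid provided the semi-axis lengths are
#' comparable; the fit is non-iterative, solved by block elimination of the
#' linear coefficients followed by a 6x6 generalized eigenproblem, keeping the
#' eigenvector on the positive side of the constraint with the smallest
#' residual.
#'
#' Points are centred on their centroid and scaled by their RMS radius before
#' fitting (raw mm-squared design columns are ill-conditioned); the transform
#' is inverted on the recovered coefficients, and the returned coefficients
#' are normalized so `kJ - I^2 = 1` in world coordinates.
#'
#' @param points A data frame with columns `x`, `y`, `z` (mm), or a 3-column
#'   matrix; at least 10 points spanning a genuinely 3D configuration.
#' @param k Constraint parameter; default 4. Values below 4 weaken the
#'   ellipsoid guarantee and are rejected.
#' @return A [quadric()] with attributes `rms_residual` (algebraic RMS
#'   residual in normalized coordinates) and `n_points`.
#' @export
#' @examples
#' sph <- phantom_sphere_points(n = 50)
#' q <- fit_quadric(sph)
#' q$k * q$J - q$I^2
fit_quadric <- function(points, k = 4) {
  P <- as_point_matrix(points)
  if (nrow(P) < 10L) {
    lf_abort(sprintf("Need at least 10 points to fit a quadric (got %d).", nrow(P)),
             "insufficient_data")
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k)) {
    lf_abort("`k` must be a single number.", "validation")
  }
  if (k < 4) {
    lf_abort("`k` < 4 is rejected: the ellipsoid-specific guarantee requires k >= 4.",
             "validation")
  }

  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  s <- sqrt(mean(rowSums(Pc^2)))
  if (s < 1e-12) lf_abort("Points are coincident.", "rank")
  Pn <- Pc / s

  x <- Pn[, 1]; y <- Pn[, 2]; z <- Pn[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * y * z, 2 * x * z, 2 * x * y, 2 * x, 2 * y, 2 * z, 1)
  if (qr(D)$rank < 9L) {
    lf_abort("Degenerate point configuration (coplanar or conic): no 3D quadric is determined.",
             "rank")
  }

  S <- crossprod(D)
  S11 <- S[1:6, 1:6]; S12 <- S[1:6, 7:10]; S22 <- S[7:10, 7:10]
  if (rcond(S22) < 1e-12) lf_abort("Degenerate point configuration.", "rank")
  T2 <- solve(S22, t(S12))
  A <- S11 - S12 %*% T2
  C1 <- constraint_block(k)

  eg <- eigen(solve(C1, A))
  u <- NULL; best_res <- Inf
  for (i in seq_along(eg$values)) {
    if (abs(Im(eg$values[i])) > 1e-8) next
    v1 <- Re(eg$vectors[, i])
    cval <- drop(t(v1) %*% C1 %*% v1)
    if (cval <= 1e-12) next
    v1 <- v1 / sqrt(cval)
    v2 <- -drop(T2 %*% v1)
    cand <- c(v1, v2)
    res <- drop(t(cand) %*% S %*% cand)
    if (res < best_res) {
      best_res <- res
      u <- cand
    }
  }
  if (is.null(u)) {
    lf_abort("No admissible eigen-solution on the positive side of the constraint: points do not determine an ellipsoid.",
             "non_ellipsoid")
  }

  co_world <- denormalize_quadric(u, ctr, s)
  # renormalize in world coordinates so kJ - I^2 = 1 (the constraint scales
  # as s^4 under coordinate scaling, so its sign survives the transform)
  q0 <- quadric(co_world, k = k)
  cval <- k * q0$J - q0$I^2
  if (cval <= 0) {
    lf_abort("Fit left the ellipsoid-admissible region after denormalization.",
             "non_ellipsoid")
  }
  q <- quadric(co_world / sqrt(cval), k = k)
  attr(q, "rms_residual") <- sqrt(max(best_res, 0) / nrow(P))
  attr(q, "n_points") <- nrow(P)
  q
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points))) {
      lf_abort("`points` data frame must have columns x, y, z.", "validation")
    }
    P <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.matrix(points) && ncol(points) == 3L) {
    P <- points
  } else {
    lf_abort("`points` must be a data frame with x, y, z or a 3-column matrix.",
             "validation")
  }
  storage.mode(P) <- "double"
  if (!all(is.finite(P))) lf_abort("Point coordinates must be finite.", "validation")
  P
}

# map coefficients fitted in normalized coordinates v = (X - ctr)/s back to X
denormalize_quadric <- function(u, ctr, s) {
  Aq <- matrix(c(u[1], u[6], u[5],
                 u[6], u[2], u[4],
                 u[5], u[4], u[3]), 3, 3)
  bq <- u[7:9]
  d <- u[10]
  A_w <- Aq / s^2
  b_w <- -A_w %*% ctr + bq / s
  d_w <- drop(t(ctr) %*% A_w %*% ctr) - 2 * drop(crossprod(bq, ctr)) / s + d
  c(A_w[1, 1], A_w[2, 2], A_w[3, 3], A_w[2, 3], A_w[1, 3], A_w[1, 2],
    b_w[1], b_w[2], b_w[3], d_w)
}

#' Convert a quadric to geometric ellipsoid parameters
#'
#' Recovers centre, semi-axes and orientation from algebraic quadric
#' coefficients. The centre solves the gradient's zero,
#' `A %*% center = -(p, q, r)`; the semi-axes are `sqrt(-d_c / lambda_i)` for
#' the eigenvalues of the quadratic-form matrix `A`, where `d_c` is the
#' centre-translated constant term. Axes are sorted descending; rotation
#' columns are the corresponding unit eigenvectors, sign-canonicalized
#' (largest-magnitude component positive) and arranged right-handed.
#'
#' @param q A [quadric()].
#' @return An [ellipsoid()].
#' @export
#' @examples
#' q <- quadric(c(1, 4, 9, 0, 0, 0, 0, 0, 0, -1))
#' quadric_to_ellipsoid(q)$semi_axes
quadric_to_ellipsoid <- function(q) {
  if (!inherits(q, "quadric")) lf_abort("`q` must be a quadric.", "validation")
  A <- quadric_matrix(q)
  if (rcond(A) < 1e-12) {
    lf_abort("Quadratic-form matrix is singular: not a central quadric.",
             "non_ellipsoid")
  }
  b <- unname(q$coef[c("p", "q", "r")])
  center <- drop(solve(A, -b))
  d_c <- unname(q$coef["d"]) + drop(crossprod(b, center))
  eg <- eigen(A, symmetric = TRUE)
  ax2 <- -d_c / eg$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) {
    lf_abort("Quadric is not an ellipsoid (hyperboloid, paraboloid or imaginary surface).",
             "non_ellipsoid")
  }
  semi <- sqrt(ax2)
  R <- eg$vectors
  ord <- order(semi, decreasing = TRUE)
  semi <- semi[ord]
  R <- R[, ord, drop = FALSE]
  # deterministic sign: largest-|component| of each axis positive; restore
  # right-handedness on the minor axis
  for (j in 1:3) {
    i_max <- which.max(abs(R[, j]))
    if (R[i_max, j] < 0) R[, j] <- -R[, j]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  ellipsoid(center, semi, R)
}

#' Surface samples a mask contributes to the ellipsoid fit
#'
#' The measured evidence about the lesion surface: the sub-pixel contour face
#' points of every occupied slice ([contour_face_points()]) plus two extent
#' poles placed half a slice profile beyond the first/last occupied slice, at
#' those slices' areal centroids. The contour rings carry the cross-section
#' shape and, through their slice-to-slice size change, the surface curvature;
#' the poles encode the through-plane extent convention — a lesion visible on
#' a slice is taken to extend half the slice profile beyond that slice centre,
#' the same convention the planimetric volume and [interpolate_z()] use.
#' Points interpolated *between* slices are deliberately not fitted: they are
#' fabrications of the interpolation kernel, not observations, and on
#' coarsely-spaced slices they systematically drag the least-squares fit away
#' from the measured cross-sections.
#'
#' @param mask A non-empty [lesion_mask()].
#' @param pole_extension Distance (mm) from the end slice centres to the
#'   extent poles; default half the slice centre spacing.
#' @return A tibble with columns `x`, `y`, `z` (mm).
#' @export
fit_sample_points <- function(mask, pole_extension = NULL) {
  check_nonempty(mask, "fit_sample_points")
  grid <- mask$grid
  step <- slice_step(grid)
  pole_extension <- pole_extension %||% (step / 2)
  rings <- contour_face_points(mask)
  occk <- which(apply(mask$occupancy, 3, any))
  zs <- grid_z(grid)
  centroid <- function(k) {
    ind <- which(mask$occupancy[, , k, drop = TRUE], arr.ind = TRUE)
    c(grid$origin[1] + (mean(ind[, 1]) - 1) * grid$dx,
      grid$origin[2] + (mean(ind[, 2]) - 1) * grid$dy)
  }
  k0 <- occk[1]; k1 <- occk[length(occk)]
  c0 <- centroid(k0); c1 <- centroid(k1)
  poles <- tibble::tibble(
    x = c(c0[1], c1[1]), y = c(c0[2], c1[2]),
    z = c(zs[k0] - pole_extension, zs[k1] + pole_extension)
  )
  dplyr::bind_rows(rings[, c("x", "y", "z")], poles)
}

#' Fit an ellipsoid to a lesion mask
#'
#' The automated 3D measurement: the mask's measured surface samples
#' ([fit_sample_points()] — per-slice sub-pixel contour points plus two
#' through-plane extent poles) are fitted with the ellipsoid-specific
#' constrained quadric ([fit_quadric()]) and converted to geometric
#' parameters ([quadric_to_ellipsoid()]). Deterministic for fixed input.
#' Works equally on the original gapped acquisition grid and on a fine grid
#' produced by [interpolate_z()] (where every 1 mm slice contributes a ring).
#'
#' The mask must span at least two occupied slices — a single-slice ROI
#' carries no through-plane shape information, so the 3D fit refuses it
#' rather than report a diameter dominated by the slice-profile convention.
#'
#' @param mask A [lesion_mask()].
#' @param k Constraint parameter passed to [fit_quadric()].
#' @param pole_extension Passed to [fit_sample_points()].
#' @return An [ellipsoid()] with attributes `quadric`, `n_points`,
#'   `rms_residual` and `mask_voxels`.
#' @export
#' @examples
#' ph <- voxelize_ellipsoid(semi_axes = c(12, 9, 7), dx = 1,
#'                          slice_thickness = 1, slice_gap = 0)
#' fit <- fit_ellipsoid(ph$mask)
#' fit$semi_axes
fit_ellipsoid <- function(mask, k = 4, pole_extension = NULL) {
  check_nonempty(mask, "fit_ellipsoid")
  n_slices <- sum(apply(mask$occupancy, 3, any))
  if (n_slices < 2L) {
    lf_abort(paste(
      "Mask occupies a single slice: the 3D ellipsoid fit needs at least two",
      "occupied slices. Acquire/segment more slices or use the 2D measurements",
      "(planimetric_volume, axial_max_diameter)."
    ), "insufficient_data")
  }
  pts <- fit_sample_points(mask, pole_extension = pole_extension)
  q <- fit_quadric(pts, k = k)
  e <- quadric_to_ellipsoid(q)
  attr(e, "quadric") <- q
  attr(e, "n_points") <- nrow(pts)
  attr(e, "rms_residual") <- attr(q, "rms_residual")
  attr(e, "mask_voxels") <- voxel_count(mask)
  e
}

#' Exact points on the unit sphere (helper for examples and tests)
#'
#' Deterministic quasi-uniform samples on a sphere via a Fibonacci lattice.
#'
#' @param n Number of points.
#' @param radius Sphere radius (default 1).
#' @param center Length-3 centre (default origin).
#' @return Tibble with columns `x`, `y`, `z`.
#' @export
phantom_sphere_points <- function(n = 50, radius = 1, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  tibble::tibble(
    x = center[1] + radius * sin(phi) * cos(theta),
    y = center[2] + radius * sin(phi) * sin(theta),
    z = center[3] + radius * cos(phi)
  )
}

#' Exact surface points of an ellipsoid
#'
#' Deterministic samples on the surface of an arbitrary ellipsoid, for
#' validating the fit against known generating parameters.
#'
#' @param e An [ellipsoid()].
#' @param n Number of points.
#' @return Tibble with columns `x`, `y`, `z` (mm).
#' @export
ellipsoid_surface_points <- function(e, n = 100) {
  u <- as.matrix(phantom_sphere_points(n))
  w <- t(e$rotation %*% (t(u) * e$semi_axes) + e$center)
  tibble::tibble(x = w[, 1], y = w[, 2], z = w[, 3])
}
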