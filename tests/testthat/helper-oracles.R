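# Independent oracles and small fixture builders used across the suite.

# Unconstrained algebraic quadric fit: smallest right singular vector of the
# design matrix (points centred/scaled the same way as the package fit), then
# geometric conversion. Independent of the constrained eigen solver.
oracle_algebraic_fit <- function(points) {
  P <- as.matrix(points[, c("x", "y", "z")])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  s <- sqrt(mean(rowSums(Pc^2)))
  Pn <- Pc / s
  x <- Pn[, 1]; y <- Pn[, 2]; z <- Pn[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * y * z, 2 * x * z, 2 * x * y, 2 * x, 2 * y, 2 * z, 1)
  u <- svd(D)$v[, 10]
  # back to world coordinates
  Aq <- matrix(c(u[1], u[6], u[5], u[6], u[2], u[4], u[5], u[4], u[3]), 3, 3)
  bq <- u[7:9]; d <- u[10]
  A_w <- Aq / s^2
  b_w <- -A_w %*% ctr + bq / s
  d_w <- drop(t(ctr) %*% A_w %*% ctr) - 2 * drop(crossprod(bq, ctr)) / s + d
  co <- c(A_w[1, 1], A_w[2, 2], A_w[3, 3], A_w[2, 3], A_w[1, 3], A_w[1, 2],
          b_w[1], b_w[2], b_w[3], d_w)
  quadric_to_ellipsoid(quadric(co))
}

# Brute-force 2D Feret diameter over all inside-pixel centre pairs (cm).
oracle_feret_cm <- function(slice, dx, dy) {
  ind <- which(slice, arr.ind = TRUE)
  pts <- cbind((ind[, 1] - 1) * dx, (ind[, 2] - 1) * dy)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2)) / 10
}

# Per-pixel signed-distance interpolation oracle for two concentric discs:
# disc radii r0 and r1 (mm) on a square pixel grid, exact radial signed
# distance, linear interpolation at fraction w.
oracle_disc_midslice <- function(r0, r1, w, n, dx) {
  ctr <- (n + 1) / 2
  xs <- ((1:n) - ctr) * dx
  rad <- sqrt(outer(xs^2, xs^2, "+"))
  sd0 <- rad - r0
  sd1 <- rad - r1
  (1 - w) * sd0 + w * sd1 <= 0
}

# circular disc ROI as a logical matrix (pixel centres within radius r of the
# centre pixel)
disc_roi <- function(n, r, dx) {
  ctr <- (n + 1) / 2
  xs <- ((1:n) - ctr) * dx
  sqrt(outer(xs^2, xs^2, "+")) <= r
}

make_block_mask <- function(nx, ny, nz, from, to, dx = 1, thickness = 3, gap = 3) {
  occ <- array(FALSE, c(nx, ny, nz))
  occ[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  lesion_mask(occ, voxel_grid(nx, ny, nz, dx = dx, slice_thickness = thickness,
                              slice_gap = gap))
}

# random semi-axes within the k = 4 constraint's applicability domain
# ("comparable semi-axes": kJ - I^2 > 0, where exact recovery is guaranteed)
random_admissible_axes <- function(lo = 5, hi = 20, k = 4) {
  repeat {
    ax <- sort(stats::runif(3, lo, hi), decreasing = TRUE)
    if (ellipsoid_constraint_value(ax, k) > 1e-6 * sum(1 / ax^2)^2) return(ax)
  }
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

grid_z_values <- function(mask) {
  g <- mask$grid
  g$origin[3] + (seq_len(g$nz) - 1) * (g$slice_thickness + g$slice_gap)
}

table2_path <- function() {
  system.file("extdata", "table2.csv", package = "lesionfit3d")
}
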