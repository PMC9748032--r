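#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ellipsoid fit
#'
#' One row per geometric parameter: semi-axes (mm), centre coordinates (mm)
#' and the derived report measurements (TMD in cm, TV in cc).
#'
#' @param x An [ellipsoid()], typically from [fit_ellipsoid()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.ellipsoid <- function(x, ...) {
  tibble::tibble(
    term = c("semi_axis_a", "semi_axis_b", "semi_axis_c",
             "center_x", "center_y", "center_z", "tmd", "tv"),
    estimate = c(x$semi_axes, x$center, ellipsoid_tmd(x), ellipsoid_volume(x)),
    unit = c(rep("mm", 6), "cm", "cc")
  )
}

#' Glance at an ellipsoid fit
#'
#' @param x An [ellipsoid()], typically from [fit_ellipsoid()].
#' @param ... Unused.
#' @return A one-row tibble with `tmd_cm`, `tv_cc`, the semi-axes and, when
#'   the ellipsoid came from [fit_ellipsoid()], `n_points` and
#'   `rms_residual` of the underlying quadric fit.
#' @export
glance.ellipsoid <- function(x, ...) {
  tibble::tibble(
    tmd_cm = ellipsoid_tmd(x),
    tv_cc = ellipsoid_volume(x),
    a_mm = x$semi_axes[1], b_mm = x$semi_axes[2], c_mm = x$semi_axes[3],
    n_points = attr(x, "n_points") %||% NA_integer_,
    rms_residual = attr(x, "rms_residual") %||% NA_real_
  )
}

#' @export
tidy.pirads_rescore <- function(x, ...) x$table

#' @export
glance.pirads_rescore <- function(x, ...) x$summary

#' Bland-Altman plot of manual vs automated measurements
#'
#' Scatter of per-subject differences (automated minus manual) against the
#' pairwise means, with the bias (solid) and 95% limits of agreement
#' (dotted) — the standard method-agreement display.
#'
#' @param table A cohort table (see [read_cohort_table()]).
#' @param measure `"tv_cc"` or `"tmd_cm"`.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(table, measure = c("tv_cc", "tmd_cm")) {
  measure <- match.arg(measure)
  tb <- validate_cohort_table(table)
  man <- tb[[paste0("manual_", measure)]]
  aut <- tb[[paste0("auto_", measure)]]
  ba <- bland_altman(man, aut)
  df <- tibble::tibble(avg = (man + aut) / 2, diff = aut - man)
  unit <- if (measure == "tv_cc") "cc" else "cm"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = "dotted") +
    ggplot2::labs(
      x = sprintf("Mean of methods (%s)", unit),
      y = sprintf("Automated 3D - manual (%s)", unit),
      title = sprintf("Bland-Altman agreement, %s", measure)
    ) +
    ggplot2::theme_minimal()
}

#' Violin plot of measurement distributions by score
#'
#' Distribution of a measurement across subjects for each initial PI-RADS
#' score, manual and automated side by side.
#'
#' @inheritParams plot_bland_altman
#' @return A ggplot object.
#' @export
plot_score_violin <- function(table, measure = c("tv_cc", "tmd_cm")) {
  measure <- match.arg(measure)
  tb <- validate_cohort_table(table)
  df <- tidyr::pivot_longer(
    tb[, c("initial_score", paste0(c("manual_", "auto_"), measure))],
    -"initial_score", names_to = "method", values_to = "value"
  )
  df$method <- ifelse(grepl("^manual", df$method), "manual 2D", "ellipsoid 3D")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$initial_score),
                                   y = .data$value, fill = .data$method)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         trim = FALSE, alpha = 0.7) +
    ggplot2::labs(x = "Initial PI-RADS score", y = measure, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ellipsoid fit over its mask
#'
#' Axial projection: boundary voxel centres of the mask with the fitted
#' ellipsoid's axial outline (its projection onto the xy plane approximated
#' by the fitted equatorial cross-section through the centre).
#'
#' @param object An [ellipsoid()] from [fit_ellipsoid()].
#' @param mask The [lesion_mask()] it was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ellipsoid <- function(object, mask = NULL, ...) {
  th <- seq(0, 2 * pi, length.out = 181)
  # axial cut through the centre: intersect the ellipsoid with z = center_z
  A <- object$rotation %*% diag(1 / object$semi_axes^2) %*% t(object$rotation)
  M2 <- A[1:2, 1:2]
  eg <- eigen(M2, symmetric = TRUE)
  r <- 1 / sqrt(eg$values)
  pts <- t(eg$vectors %*% rbind(r[1] * cos(th), r[2] * sin(th)))
  df <- tibble::tibble(x = pts[, 1] + object$center[1],
                       y = pts[, 2] + object$center[2])
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    bp <- boundary_points(mask)
    p <- p + ggplot2::geom_point(data = bp, ggplot2::aes(x = .data$x, y = .data$y),
                                 alpha = 0.3, size = 0.8)
  }
  p +
    ggplot2::geom_path(data = df, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Fitted ellipsoid, axial section") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
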