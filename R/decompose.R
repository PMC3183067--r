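#' Tube axis model
#'
#' Direction of a straight tube in the image plane, as an angle in
#' `(-pi/2, pi/2]` measured from the x-axis, plus the centroid the fitted
#' line passes through.
#'
#' @param angle Axis angle (rad), normalized into `(-pi/2, pi/2]`.
#' @param centroid Numeric length-2 `(x, y)` point on the axis (um).
#' @return An object of class `axis_model`.
#' @export
axis_model <- function(angle, centroid = c(0, 0)) {
  stopifnot(is.numeric(angle), length(angle) == 1, is.finite(angle))
  angle <- ((angle + pi / 2) %% pi) - pi / 2
  if (angle == -pi / 2) angle <- pi / 2
  structure(
    list(
      angle = angle,
      centroid = as.numeric(centroid),
      intercept = if (abs(cos(angle)) > 1e-12) {
        centroid[2] - tan(angle) * centroid[1]
      } else {
        NA_real_
      }
    ),
    class = "axis_model"
  )
}

#' @export
print.axis_model <- function(x, ...) {
  cat(sprintf("<axis_model> angle %.4f rad (%.2f deg), centroid (%.4g, %.4g) um\n",
              x$angle, x$angle * 180 / pi, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Estimate the tube axis from a localization cloud
#'
#' Fits a straight line to all detected positions by total least squares
#' (the principal axis of the position covariance), which treats x and y
#' symmetrically and is therefore invariant to the tube's orientation in
#' the image -- unlike ordinary regression of y on x.
#'
#' An isotropic cloud has no meaningful axis; if the ratio of the two
#' singular values of the centred cloud falls below `min_aspect` the fit
#' is rejected.
#'
#' @param cloud Tibble (or data frame) of positions with columns `x_um`,
#'   `y_um`; at least 2 non-coincident points.
#' @param min_aspect Minimum major/minor axis SD ratio required for a
#'   well-defined direction (default 2).
#' @return An [axis_model()].
#' @export
estimate_axis <- function(cloud, min_aspect = 2) {
  check_trajectory_cols(cloud, c("x_um", "y_um"))
  P <- cbind(cloud$x_um, cloud$y_um)
  P <- P[stats::complete.cases(P), , drop = FALSE]
  if (nrow(P) < 2) abort("Axis estimation needs at least 2 points.")
  ctr <- colMeans(P)
  C <- sweep(P, 2, ctr)
  if (all(abs(C) < 1e-12)) {
    abort("All points are coincident; the axis direction is undefined.")
  }
  sv <- svd(C, nu = 0)
  v1 <- sv$v[, 1]
  if (sv$d[2] > 0 && sv$d[1] / sv$d[2] < min_aspect) {
    warn(sprintf(
      "Localization cloud is nearly isotropic (aspect %.2f < %.2f); the fitted axis direction is poorly defined.",
      sv$d[1] / sv$d[2], min_aspect
    ))
  }
  axis_model(atan2(v1[2], v1[1]), centroid = ctr)
}

#' Decompose a trajectory into longitudinal and transversal components
#'
#' Rotates in-plane coordinates so the first coordinate runs along the
#' tube axis: `long = cos(a)*x + sin(a)*y`, `transv = -sin(a)*x +
#' cos(a)*y`. The rotation is orthogonal, so step lengths are preserved
#' and the 1D MSDs of the two components sum exactly to the 2D MSD at
#' every lag. For `a = pi/2` this gives `long = y`, `transv = -x`.
#'
#' @param traj Localization tibble with `x_um`, `y_um`.
#' @param axis An [axis_model()] (e.g. from [estimate_axis()]).
#' @return `traj` with added columns `long_um` and `transv_um`.
#' @export
decompose_trajectory <- function(traj, axis) {
  stopifnot(inherits(axis, "axis_model"))
  check_trajectory_cols(traj, c("x_um", "y_um"))
  ca <- cos(axis$angle); sa <- sin(axis$angle)
  dplyr::mutate(
    traj,
    long_um = ca * .data$x_um + sa * .data$y_um,
    transv_um = -sa * .data$x_um + ca * .data$y_um
  )
}

#' Curvature-free diffusion estimate from the longitudinal component
#'
#' Displacements parallel to the tube axis are unaffected by membrane
#' curvature, so a 1D MSD of the longitudinal component fitted with
#' `MSD(t) = 2*D*t + b` recovers the true diffusion coefficient without
#' geometric bias -- unlike fits on projected 2D displacements, which
#' underestimate it.
#'
#' @inheritParams decompose_trajectory
#' @param fit_points Integer lags for the fit (default `2:5`).
#' @param max_lag Largest MSD lag (default covers the fit range).
#' @return A `diffusion_fit` tibble (one row per trajectory).
#' @export
estimate_longitudinal_D <- function(traj, axis, fit_points = 2:5,
                                    max_lag = max(fit_points)) {
  dec <- decompose_trajectory(traj, axis)
  dec$x_um <- dec$long_um
  msd <- compute_msd(dec, max_lag = max_lag, coords = "x")
  fit_diffusion(msd, dimensionality = 1, fit_points = fit_points)
}
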