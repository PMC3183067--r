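#' Compute time-averaged mean squared displacement
#'
#' For each trajectory in `traj`, computes the time-averaged MSD
#' `MSD(n*dt) = (N-n)^-1 * sum_i |r_(i+n) - r_i|^2` over all start frames,
#' for lags `n = 1..max_lag`. Lags are counted in *frame* units, so
#' trajectories with blinking gaps contribute each surviving pair at its
#' true lag (pairs spanning a gap are simply absent and `n_pairs` drops
#' accordingly).
#'
#' `coords = "xy"` uses the two in-plane coordinates (planar or projected
#' trajectories); `coords = "xyz"` sums squared displacements over the
#' three Cartesian coordinates and is the appropriate choice for
#' trajectories on cylindrical surfaces (the 3D-SPT readout). `coords =
#' "x"` or `"y"` give the one-dimensional MSD of a single coordinate.
#'
#' @param traj Localization tibble with columns `frame`, `t_s`, `x_um`,
#'   `y_um` (and `z_um` for `"xyz"`). May contain several trajectories
#'   and/or geometries; the result is computed per group of the identifier
#'   columns present among `D_sim`, `dt_s`, `diameter_um`, `geometry`,
#'   `trajectory_id`.
#' @param max_lag Largest lag in frames. Default: a quarter of the
#'   shortest trajectory, the usual SPT compromise between lag coverage
#'   and estimator variance.
#' @param coords Coordinate set: `"xy"` (default), `"xyz"`, `"x"` or `"y"`.
#'
#' @return A tibble of class `msd_curve` with the grouping columns plus
#'   `lag` (frames), `lag_s`, `msd_um2`, `n_pairs` and `dispersion_um2`
#'   (SD of the squared displacements at that lag). `dim_label` records
#'   the coordinate set.
#'
#' @examples
#' traj <- simulate_planar_trajectory(0.2, 0.02, 400, seed = 3)
#' msd <- compute_msd(traj, max_lag = 10)
#' fit_diffusion(msd)
#' @export
compute_msd <- function(traj, max_lag = NULL, coords = c("xy", "xyz", "x", "y")) {
  coords <- match.arg(coords)
  cols <- switch(coords,
    xy = c("x_um", "y_um"),
    xyz = c("x_um", "y_um", "z_um"),
    x = "x_um",
    y = "y_um"
  )
  check_trajectory_cols(traj, c("frame", "t_s", cols))
  keys <- intersect(
    c("D_sim", "dt_s", "diameter_um", "geometry", "trajectory_id"),
    names(traj)
  )
  out <- traj |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      msd_single(g$frame, g$t_s, as.matrix(g[cols]), max_lag)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(dim_label = switch(coords, xy = "2D", xyz = "3Dcoords", "1D"))
  new_msd_curve(out)
}

#' One-dimensional MSD of a single coordinate series
#'
#' Convenience wrapper around the frame-aware MSD kernel for a bare
#' numeric series sampled at a constant frame interval.
#'
#' @param series Numeric coordinate sequence (um).
#' @param dt Frame interval (s).
#' @param max_lag Largest lag in frames (default a quarter of the series).
#' @return A tibble of class `msd_curve` (columns as in [compute_msd()]).
#' @export
compute_msd_1d <- function(series, dt, max_lag = NULL) {
  stopifnot(is.numeric(series), length(series) >= 2, dt > 0)
  frames <- seq_along(series) - 1L
  out <- msd_single(frames, frames * dt, matrix(series, ncol = 1), max_lag)
  new_msd_curve(dplyr::mutate(out, dim_label = "1D"))
}

# Frame-indexed MSD kernel. Positions are scattered into vectors indexed
# by frame so that blink gaps become NA rows and every pair is counted at
# its true frame lag.
msd_single <- function(frame, t_s, pos, max_lag) {
  ord <- order(frame)
  frame <- frame[ord]; t_s <- t_s[ord]; pos <- pos[ord, , drop = FALSE]
  n_frames <- max(frame) - min(frame) + 1L
  dt <- if (length(t_s) >= 2) {
    diff(range(t_s)) / (max(frame) - min(frame))
  } else {
    NA_real_
  }
  if (is.null(max_lag)) max_lag <- max(1L, floor((n_frames - 1L) / 4))
  if (max_lag < 1 || max_lag >= n_frames) {
    abort("`max_lag` must satisfy 1 <= max_lag < the trajectory frame span.")
  }
  idx <- frame - min(frame) + 1L
  M <- matrix(NA_real_, nrow = n_frames, ncol = ncol(pos))
  M[idx, ] <- pos
  purrr::map_dfr(seq_len(max_lag), function(l) {
    d <- M[(l + 1):n_frames, , drop = FALSE] - M[1:(n_frames - l), , drop = FALSE]
    sq <- rowSums(d^2)
    ok <- !is.na(sq)
    k <- sum(ok)
    tibble::tibble(
      lag = l,
      lag_s = l * dt,
      msd_um2 = if (k > 0) mean(sq[ok]) else NA_real_,
      n_pairs = k,
      dispersion_um2 = if (k > 1) stats::sd(sq[ok]) else NA_real_
    )
  })
}

new_msd_curve <- function(tbl) {
  class(tbl) <- unique(c("msd_curve", class(tbl)))
  tbl
}

#' Average MSD curves over an ensemble of trajectories
#'
#' Collapses per-trajectory MSD curves to an ensemble mean per lag (and
#' per any remaining grouping column such as `geometry`), with the
#' standard error over trajectories as the dispersion.
#'
#' @param msd An `msd_curve` tibble containing a `trajectory_id` column.
#' @return An `msd_curve` tibble with `msd_um2` the across-trajectory
#'   mean, `n_pairs` the number of contributing trajectories, and
#'   `dispersion_um2` the standard error of the mean.
#' @export
ensemble_msd <- function(msd) {
  stopifnot("trajectory_id" %in% names(msd))
  keys <- setdiff(
    intersect(c("D_sim", "dt_s", "diameter_um", "geometry", "dim_label",
                "lag", "lag_s"), names(msd)),
    character()
  )
  out <- msd |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$msd_um2)),
      dispersion_um2 = stats::sd(.data$msd_um2, na.rm = TRUE) /
        sqrt(max(1, sum(!is.na(.data$msd_um2)))),
      msd_um2 = mean(.data$msd_um2, na.rm = TRUE),
      .groups = "drop"
    )
  new_msd_curve(out)
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of `MSD(t) = 4*D*t + b` (two dimensions) or
#' `MSD(t) = 2*D*t + b` (one dimension) on a short initial stretch of the
#' MSD curve -- by default points 2 to 5, i.e. lags `2*dt` through `5*dt`.
#' Restricting the fit to early lags keeps the estimate local in time and
#' avoids the strongly correlated, high-variance tail of time-averaged MSD
#' curves. The offset `b` absorbs static and dynamic localization errors
#' and may legitimately be negative.
#'
#' Trajectories with fitted `D` below `1e-4` um^2/s are classified as
#' immobile: below that value the apparent motion of a typical SPT
#' experiment is indistinguishable from localization noise.
#'
#' @param msd An `msd_curve` tibble (one or many trajectories/groups).
#' @param dimensionality 1 or 2; when `NULL` (default) it is inferred from
#'   `dim_label` (`"1D"` maps to 1; `"2D"` and `"3Dcoords"` map to 2, the
#'   appropriate convention for motion on a two-dimensional surface
#'   whatever the embedding).
#' @param fit_points Integer lags used in the fit (default `2:5`).
#' @param immobile_threshold Mobility cutoff for `D` (um^2/s).
#'
#' @return A tibble of class `diffusion_fit`: grouping columns plus
#'   `D_um2_s`, `b_um2`, `fit_dimensionality`, `mobility`, `n_fit_points`,
#'   `r_squared`.
#' @export
fit_diffusion <- function(msd, dimensionality = NULL, fit_points = 2:5,
                          immobile_threshold = 1e-4) {
  stopifnot(is.numeric(fit_points), length(fit_points) >= 2)
  keys <- intersect(
    c("D_sim", "dt_s", "diameter_um", "geometry", "trajectory_id"),
    names(msd)
  )
  infer_dim <- function(lbl) {
    if (!is.null(dimensionality)) return(as.integer(dimensionality))
    if (identical(lbl, "1D")) 1L else 2L
  }
  out <- msd |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      if (!all(fit_points %in% g$lag)) {
        abort(paste0(
          "MSD curve has fewer lags than the requested fit range (need lags ",
          paste(range(fit_points), collapse = "-"), ")."
        ))
      }
      sub <- g[match(fit_points, g$lag), ]
      dim_fit <- infer_dim(sub$dim_label[1] %||% "2D")
      fit <- stats::lm(msd_um2 ~ lag_s, data = sub)
      slope <- stats::coef(fit)[["lag_s"]]
      D <- slope / (2 * dim_fit)
      sst <- sum((sub$msd_um2 - mean(sub$msd_um2))^2)
      ssr <- sum(stats::residuals(fit)^2)
      tibble::tibble(
        D_um2_s = D,
        b_um2 = stats::coef(fit)[["(Intercept)"]],
        fit_dimensionality = dim_fit,
        mobility = ifelse(D < immobile_threshold, "immobile", "mobile"),
        n_fit_points = length(fit_points),
        r_squared = if (sst > 0) 1 - ssr / sst else NA_real_
      )
    }) |>
    dplyr::ungroup()
  class(out) <- unique(c("diffusion_fit", class(out)))
  out
}

#' Discard short trajectories
#'
#' Retains trajectories with at least `min_points` localizations.
#' Typical cutoffs are 30 points for bright probes on artificial tubes and
#' 100 points for tracking on cells, where shorter tracks give unreliable
#' time-averaged MSDs.
#'
#' @param traj Localization tibble with a `trajectory_id` column (grouped
#'   additionally by any of `D_sim`, `dt_s`, `diameter_um`, `geometry`
#'   present).
#' @param min_points Minimum number of localizations (inclusive).
#' @return The filtered tibble.
#' @export
filter_trajectories <- function(traj, min_points) {
  stopifnot(min_points >= 1)
  if (nrow(traj) == 0) return(traj)
  keys <- intersect(
    c("D_sim", "dt_s", "diameter_um", "geometry", "trajectory_id"),
    names(traj)
  )
  traj |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(dplyr::n() >= min_points) |>
    dplyr::ungroup()
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    n_trajectories = nrow(x),
    mean_D_um2_s = mean(x$D_um2_s),
    sd_D_um2_s = stats::sd(x$D_um2_s),
    median_D_um2_s = stats::median(x$D_um2_s),
    fraction_mobile = mean(x$mobility == "mobile")
  )
}
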