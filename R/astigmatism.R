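#' Build an astigmatism z-calibration
#'
#' With a cylindrical lens in the detection path, a point emitter's image
#' is circular in focus and elliptical above/below focus, with the
#' ellipticity `wx/wy` varying monotonically with axial position over a
#' limited range (~400 nm in typical configurations, with 50-70 nm axial
#' accuracy). This function turns a measured calibration series of spot
#' widths at known stage positions into an invertible ratio-to-z map.
#'
#' Only the maximal contiguous sub-range over which `wx/wy` is strictly
#' monotone is retained (defocus far from focus turns the curve over, so
#' the tails carry no usable information). Inside that range the map is a
#' monotone piecewise-cubic (Fritsch-Carlson) interpolant, which passes
#' exactly through the calibration nodes and cannot overshoot between
#' them.
#'
#' @param samples Tibble/data frame with columns `z_nm`, `wx`, `wy`
#'   (widths in any common unit; only their ratio is used), at least 5
#'   distinct z positions.
#' @param accuracy_nm Documented axial localization accuracy stored as
#'   metadata (default `c(50, 70)`).
#' @return An object of class `z_calibration` with the retained
#'   calibration table, the valid z and ratio ranges, and the
#'   interpolant. Supports [tidy()] and [glance()].
#' @export
build_z_calibration <- function(samples, accuracy_nm = c(50, 70)) {
  check_trajectory_cols(samples, c("z_nm", "wx", "wy"))
  tbl <- tibble::tibble(
    z_nm = samples$z_nm,
    ratio = samples$wx / samples$wy
  ) |>
    dplyr::arrange(.data$z_nm)
  if (nrow(tbl) < 5) {
    abort("A z calibration needs at least 5 distinct z positions.")
  }
  d <- diff(tbl$ratio)
  if (all(d == 0)) {
    abort("wx/wy is constant: the calibration carries no z information.")
  }
  # longest contiguous run of strictly same-signed ratio increments
  sgn <- sign(d)
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values != 0)
  if (length(keep) == 0) abort("wx/wy is nowhere strictly monotone in z.")
  best <- keep[which.max(runs$lengths[keep])]
  i0 <- starts[best]; i1 <- ends[best] + 1L
  if (i1 - i0 + 1L < 5) {
    abort("No strictly monotone stretch of at least 5 calibration points in wx/wy.")
  }
  if (i1 - i0 + 1L < nrow(tbl)) {
    warn(sprintf(
      "wx/wy is only monotone over z in [%g, %g] nm; %d calibration point(s) outside this range were dropped.",
      tbl$z_nm[i0], tbl$z_nm[i1], nrow(tbl) - (i1 - i0 + 1L)
    ))
  }
  tbl <- tbl[i0:i1, ]
  fun <- stats::splinefun(tbl$ratio, tbl$z_nm, method = "monoH.FC")
  structure(
    list(
      table = tbl,
      z_range_nm = range(tbl$z_nm),
      ratio_range = range(tbl$ratio),
      accuracy_nm = accuracy_nm,
      interpolant = fun
    ),
    class = "z_calibration"
  )
}

#' @export
print.z_calibration <- function(x, ...) {
  cat(sprintf(
    "<z_calibration> %d nodes; valid z [%g, %g] nm; wx/wy in [%.3f, %.3f]; accuracy %s nm\n",
    nrow(x$table), x$z_range_nm[1], x$z_range_nm[2],
    x$ratio_range[1], x$ratio_range[2],
    paste(x$accuracy_nm, collapse = "-")
  ))
  invisible(x)
}

#' @export
tidy.z_calibration <- function(x, ...) x$table

#' @export
glance.z_calibration <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$table),
    z_min_nm = x$z_range_nm[1], z_max_nm = x$z_range_nm[2],
    z_span_nm = diff(x$z_range_nm),
    accuracy_lo_nm = x$accuracy_nm[1], accuracy_hi_nm = x$accuracy_nm[2]
  )
}

#' Axial position from spot widths
#'
#' Maps measured spot widths through a [build_z_calibration()]
#' interpolant. Ratios outside the calibrated range are flagged as `NA`
#' rather than extrapolated: beyond the monotone range the ellipticity
#' no longer determines z.
#'
#' @param wx,wy Spot widths (same unit as the calibration), vectorized.
#' @param calib A `z_calibration`.
#' @return Numeric vector of z positions (nm), `NA` where out of range.
#' @export
z_from_widths <- function(wx, wy, calib) {
  stopifnot(inherits(calib, "z_calibration"), length(wx) == length(wy))
  ratio <- wx / wy
  z <- calib$interpolant(ratio)
  oob <- !is.finite(ratio) |
    ratio < calib$ratio_range[1] | ratio > calib$ratio_range[2]
  z[oob] <- NA_real_
  z
}

#' Attach astigmatism-derived z positions to a 2D trajectory
#'
#' Converts per-frame spot widths to z via the calibration and joins them
#' to the trajectory, turning a 2D track into the 3D-SPT readout. Frames
#' whose ellipticity falls outside the calibrated range are either
#' dropped (`action = "drop"`, leaving a blink-like gap that downstream
#' MSD handles by frame-indexed lags) or kept with `z_um = NA`
#' (`action = "mask"`).
#'
#' @param traj Planar trajectory tibble (one or more trajectories).
#' @param widths Tibble aligned row-for-row with `traj`, columns `wx`,
#'   `wy`.
#' @param calib A `z_calibration`.
#' @param action `"drop"` or `"mask"` for out-of-range frames.
#' @return `traj` with a `z_um` column added (z converted from nm).
#' @export
attach_z <- function(traj, widths, calib, action = c("drop", "mask")) {
  action <- match.arg(action)
  check_trajectory_cols(traj, c("frame", "t_s", "x_um", "y_um"))
  check_trajectory_cols(widths, c("wx", "wy"))
  if (nrow(widths) != nrow(traj)) {
    abort(sprintf(
      "`widths` (%d rows) must align row-for-row with `traj` (%d rows).",
      nrow(widths), nrow(traj)
    ))
  }
  z_nm <- z_from_widths(widths$wx, widths$wy, calib)
  out <- dplyr::mutate(traj, z_um = z_nm / 1000)
  if (action == "drop") {
    n_bad <- sum(is.na(out$z_um))
    out <- dplyr::filter(out, !is.na(.data$z_um))
    if (nrow(out) == 0) {
      warn("All frames fell outside the calibrated z range; returning an empty trajectory.")
    } else if (n_bad > 0) {
      warn(sprintf("%d frame(s) outside the calibrated z range were dropped.", n_bad))
    }
  }
  out
}
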