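#' Plot an MSD curve
#'
#' MSD against lag time, with a ribbon for the per-lag dispersion where
#' available; facetted by geometry when several geometries are present.
#'
#' @param object An `msd_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msd_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$msd_um2))
  if ("trajectory_id" %in% names(object) &&
      dplyr::n_distinct(object$trajectory_id) > 1) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = .data$trajectory_id), alpha = 0.3
    )
  } else {
    if (all(is.finite(object$dispersion_um2))) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$msd_um2 - .data$dispersion_um2,
                     ymax = .data$msd_um2 + .data$dispersion_um2),
        alpha = 0.2
      )
    }
    p <- p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8)
  }
  if ("geometry" %in% names(object) &&
      dplyr::n_distinct(object$geometry) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$geometry))
  }
  p + ggplot2::labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2)))
}

#' Plot a fitted transverse tube profile
#'
#' Density-normalized histogram of transverse localization coordinates
#' overlaid with the fitted smeared projection profile; vertical lines
#' mark the fitted tube edges.
#'
#' @param object A `tube_fit` from [fit_transverse_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tube_fit <- function(object, ...) {
  h <- object$histogram
  grid <- tibble::tibble(
    y_um = seq(min(h$y_um), max(h$y_um), length.out = 400)
  )
  grid$density <- convolved_profile(grid$y_um, object$diameter_um,
                                    object$w_um, object$y_c_um)
  edges <- object$y_c_um + c(-1, 1) * object$diameter_um / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$y_um, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_width %||% NULL, fill = "grey80") +
    ggplot2::geom_line(data = grid, colour = "#5B2C83", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = edges, linetype = "dashed") +
    ggplot2::labs(
      x = "transverse position (um)", y = expression(density ~ (mu * m^{-1})),
      title = sprintf("diameter %.0f nm, smearing %.0f nm",
                      1000 * object$diameter_um, 1000 * object$w_um)
    )
}

#' Plot the curvature-bias master curves
#'
#' Mean measured-to-true D ratio against the dimensionless parameter
#' `epsilon`, for projected (2D SPT) and cylindrical (3D SPT) readouts.
#' All simulated grid cells are shown as points; the binned monotone
#' master curves as lines.
#'
#' @param table A `bias_table`; defaults to the bundled master table.
#' @return A ggplot object.
#' @export
plot_bias_map <- function(table = NULL) {
  tbl <- table %||% bias_master()
  long <- tbl |>
    dplyr::select("epsilon", projected = "mean_ratio_proj",
                  cylindrical = "mean_ratio_cyl") |>
    tidyr::pivot_longer(-"epsilon", names_to = "mode", values_to = "ratio")
  curves <- dplyr::bind_rows(
    dplyr::mutate(master_curve("projected", tbl), mode = "projected"),
    dplyr::mutate(master_curve("cylindrical", tbl), mode = "cylindrical")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epsilon, y = .data$ratio,
                                     colour = .data$mode)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(
      data = dplyr::mutate(curves, epsilon = 10^.data$le),
      ggplot2::aes(y = .data$r_mono), linewidth = 0.9
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(epsilon == 4 * D * dt / O^2),
                  y = "measured D / true D", colour = NULL)
}
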