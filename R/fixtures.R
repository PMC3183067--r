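#' Specification of a synthetic tube SPT dataset
#'
#' Describes one emulated quantum-dot SPT experiment on a membrane tube:
#' Brownian motion on a cylinder, projected to the imaging plane at an
#' arbitrary in-plane axis angle, with additive Gaussian localization
#' noise and blinking dropouts. Defaults emulate QD tracking on pulled
#' membrane tubes: D = 0.25 um^2/s (lipid-scale mobility on a tube),
#' 300 nm diameter, 15.7 ms frame interval, 1000 frames, ~10 nm lateral
#' and ~60 nm axial localization noise.
#'
#' @param D Diffusion coefficient (um^2/s).
#' @param diameter Tube diameter (um).
#' @param dt Frame interval (s).
#' @param n_trajectories Number of trajectories.
#' @param n_frames Frames per trajectory (before blinking losses).
#' @param xy_noise_um Lateral localization noise SD (um).
#' @param z_noise_um Axial localization noise SD (um), used when a 3D
#'   readout is generated.
#' @param blink_prob Independent per-frame dropout probability.
#' @param axis_angle Tube axis direction in the image plane (rad).
#' @param seed Master seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(D = 0.25, diameter = 0.3, dt = 0.0157,
                         n_trajectories = 10, n_frames = 1000,
                         xy_noise_um = 0.010, z_noise_um = 0.060,
                         blink_prob = 0.1, axis_angle = 0, seed = 1L) {
  if (any(c(D, diameter, dt, n_trajectories, n_frames) <= 0)) {
    abort("D, diameter, dt, n_trajectories and n_frames must be positive.")
  }
  if (xy_noise_um < 0 || z_noise_um < 0) {
    abort("Noise SDs must be non-negative.")
  }
  if (blink_prob < 0 || blink_prob >= 1) {
    abort("`blink_prob` must be in [0, 1).")
  }
  structure(
    list(
      D = D, diameter = diameter, dt = dt,
      n_trajectories = as.integer(n_trajectories),
      n_frames = as.integer(n_frames),
      xy_noise_um = xy_noise_um, z_noise_um = z_noise_um,
      blink_prob = blink_prob, axis_angle = axis_angle,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic tube SPT dataset with ground truth
#'
#' Composes the Monte Carlo engine with the imaging imperfections of a
#' real SPT experiment: each trajectory is Brownian motion wrapped on a
#' cylinder, projected to the plane (optionally keeping the noisy z
#' readout), rotated so the tube axis makes `axis_angle` with the image
#' x-axis, blurred with Gaussian localization noise, and thinned by
#' independent per-frame blinking. With zero noise, zero blinking and
#' axis angle 0 the output reduces exactly to
#' [project_to_plane()] of the wrapped walk.
#'
#' @param spec A [fixture_spec()].
#' @param keep_z If `TRUE` include a `z_um` column: the true cylinder z
#'   plus axial noise, emulating a 3D-SPT (astigmatism) readout.
#' @return A list with elements `trajectories` (localization tibble with
#'   columns `trajectory_id`, `frame`, `t_s`, `x_um`, `y_um`, optionally
#'   `z_um`) and `truth` (one-row tibble: the generating parameters).
#' @export
generate_tube_dataset <- function(spec, keep_z = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  ca <- cos(spec$axis_angle); sa <- sin(spec$axis_angle)
  trajs <- purrr::map_dfr(seq_len(spec$n_trajectories), function(k) {
    set.seed(child_seed(spec$seed, 1L, k))
    theta0 <- stats::runif(1, 0, 2 * pi)
    planar <- simulate_planar_trajectory(spec$D, spec$dt,
                                         spec$n_frames - 1L,
                                         particle_id = k)
    proj <- project_to_plane(wrap_on_cylinder(planar, spec$diameter,
                                              initial_angle = theta0))
    n <- nrow(proj)
    x <- ca * proj$x_um - sa * proj$y_um
    y <- sa * proj$x_um + ca * proj$y_um
    if (spec$xy_noise_um > 0) {
      x <- x + stats::rnorm(n, 0, spec$xy_noise_um)
      y <- y + stats::rnorm(n, 0, spec$xy_noise_um)
    }
    out <- tibble::tibble(
      trajectory_id = k, frame = proj$frame, t_s = proj$t_s,
      x_um = x, y_um = y
    )
    if (keep_z) {
      cylz <- wrap_on_cylinder(planar, spec$diameter,
                               initial_angle = theta0)$z_um
      out$z_um <- cylz +
        if (spec$z_noise_um > 0) stats::rnorm(n, 0, spec$z_noise_um) else 0
    }
    if (spec$blink_prob > 0) {
      visible <- stats::runif(n) >= spec$blink_prob
      visible[1] <- TRUE # a trajectory begins at a detected spot
      out <- out[visible, ]
    }
    out
  })
  list(
    trajectories = trajs,
    truth = tibble::tibble(
      D = spec$D, diameter_um = spec$diameter, dt_s = spec$dt,
      axis_angle = spec$axis_angle, xy_noise_um = spec$xy_noise_um,
      z_noise_um = spec$z_noise_um, blink_prob = spec$blink_prob,
      seed = spec$seed
    )
  )
}
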