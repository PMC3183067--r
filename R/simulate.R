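#' Simulate a planar Brownian trajectory
#'
#' Generates one free Brownian random walk on a flat plane. The x and y
#' components of each displacement step are drawn from two independent
#' normal distributions with mean zero and variance `2 * D * dt`, so the
#' ensemble 2D MSD grows as `4*D*t`. The walk starts at the origin;
#' absolute position is irrelevant to all displacement statistics.
#'
#' @param D Diffusion coefficient (um^2/s), `>= 0`.
#' @param dt Frame interval (s), `> 0`.
#' @param n_steps Number of displacement steps (the trajectory has
#'   `n_steps + 1` localizations).
#' @param seed Optional integer seed. When supplied the trajectory is a
#'   pure function of `(D, dt, n_steps, seed)`; when `NULL` the current
#'   RNG state is used.
#' @param particle_id Identifier stored in the `trajectory_id` column.
#'
#' @return A tibble with columns `trajectory_id`, `frame` (0-based),
#'   `t_s`, `x_um`, `y_um`.
#'
#' @examples
#' traj <- simulate_planar_trajectory(D = 0.5, dt = 0.015, n_steps = 200, seed = 1)
#' head(traj)
#' @export
simulate_planar_trajectory <- function(D, dt, n_steps, seed = NULL,
                                       particle_id = 1L) {
  stopifnot(length(D) == 1, length(dt) == 1, length(n_steps) == 1)
  if (!is.finite(D) || D < 0) {
    abort("`D` must be a finite non-negative diffusion coefficient (um^2/s).")
  }
  if (!is.finite(dt) || dt <= 0) {
    abort("`dt` must be a strictly positive frame interval in seconds.")
  }
  if (n_steps < 1) abort("`n_steps` must be at least 1.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sd_step <- sqrt(2 * D * dt)
  dx <- stats::rnorm(n_steps, mean = 0, sd = sd_step)
  dy <- stats::rnorm(n_steps, mean = 0, sd = sd_step)
  n <- n_steps + 1L
  tibble::tibble(
    trajectory_id = rep(particle_id, n),
    frame = 0:(n - 1L),
    t_s = (0:(n - 1L)) * dt,
    x_um = c(0, cumsum(dx)),
    y_um = c(0, cumsum(dy))
  )
}

#' Envelope a planar trajectory onto a cylinder
#'
#' Wraps a planar random walk onto the surface of a cylinder whose axis is
#' parallel to the x-axis. Longitudinal (x) displacements are unchanged;
#' each transverse displacement is converted to an angular increment
#' `d_theta = d_y / (diameter/2)`, i.e. the planar y-distance becomes arc
#' length on the circumference. Cartesian coordinates on the cylinder are
#' then `y = (diameter/2) * cos(theta)` and `z = (diameter/2) * sin(theta)`.
#'
#' The unrolling map is an isometry: each step's geodesic length on the
#' cylinder, `sqrt(dx^2 + (diameter/2)^2 dtheta^2)`, equals the planar step
#' length exactly. `theta` is stored unwrapped (cumulative, no modulo) so
#' the transverse arc-length history is preserved; wrapping is applied only
#' through the cosine/sine map.
#'
#' @param traj A planar trajectory tibble (columns `frame`, `t_s`, `x_um`,
#'   `y_um`; one trajectory).
#' @param diameter Cylinder diameter (um), `> 0`.
#' @param initial_angle Angle assigned to the first point: `"random"`
#'   (uniform on `[0, 2*pi)`, the default) or a fixed value in radians.
#' @param seed Optional seed used only when `initial_angle = "random"`.
#'
#' @return A tibble with columns `trajectory_id`, `frame`, `t_s`, `x_um`,
#'   `theta`, `y_um`, `z_um`, `diameter_um`.
#'
#' @examples
#' p <- simulate_planar_trajectory(1, 0.015, 100, seed = 2)
#' cyl <- wrap_on_cylinder(p, diameter = 0.2, initial_angle = 0)
#' all.equal(cyl$y_um^2 + cyl$z_um^2, rep(0.01, 101))
#' @export
wrap_on_cylinder <- function(traj, diameter, initial_angle = "random",
                             seed = NULL) {
  if (!is.finite(diameter) || diameter <= 0) {
    abort("`diameter` must be a strictly positive cylinder diameter in um.")
  }
  check_trajectory_cols(traj, c("frame", "t_s", "x_um", "y_um"))
  if (identical(initial_angle, "random")) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    theta0 <- stats::runif(1, 0, 2 * pi)
  } else {
    stopifnot(is.numeric(initial_angle), length(initial_angle) == 1)
    theta0 <- initial_angle
  }
  radius <- diameter / 2
  theta <- theta0 + c(0, cumsum(diff(traj$y_um) / radius))
  tibble::tibble(
    trajectory_id = traj$trajectory_id,
    frame = traj$frame,
    t_s = traj$t_s,
    x_um = traj$x_um,
    theta = theta,
    y_um = radius * cos(theta),
    z_um = radius * sin(theta),
    diameter_um = diameter
  )
}

#' Project a cylindrical trajectory onto the imaging plane
#'
#' Drops the z coordinate, emulating what a 2D SPT experiment records when
#' the tube axis lies in the focal plane. The projected transverse
#' coordinate is bounded by the tube radius: `|y| <= diameter/2`.
#'
#' @param cyl A cylinder trajectory from [wrap_on_cylinder()].
#' @return A planar trajectory tibble (`trajectory_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`).
#' @export
project_to_plane <- function(cyl) {
  check_trajectory_cols(cyl, c("frame", "t_s", "x_um", "y_um", "z_um"))
  tibble::tibble(
    trajectory_id = cyl$trajectory_id,
    frame = cyl$frame,
    t_s = cyl$t_s,
    x_um = cyl$x_um,
    y_um = cyl$y_um
  )
}

#' Simulation grid configuration
#'
#' Describes a grid of simulation conditions. The defaults reproduce the
#' standard SPT survey grid: diffusivities 0.001-1 um^2/s, frame intervals
#' 5-100 ms, tube diameters 50-5000 nm, 50 trajectories of 1000 steps per
#' condition.
#'
#' @param D Vector of diffusivities (um^2/s).
#' @param dt Vector of frame intervals (s).
#' @param diameter Vector of cylinder diameters (um).
#' @param n_trajectories Trajectories per grid cell.
#' @param n_steps Displacement steps per trajectory.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(D = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5, 1),
                              dt = c(0.005, 0.015, 0.030, 0.050, 0.075, 0.100),
                              diameter = c(0.05, 0.1, 0.2, 0.5, 0.7, 1, 2, 5),
                              n_trajectories = 50,
                              n_steps = 1000,
                              seed = 1L) {
  vals <- c(D, dt, diameter, n_trajectories, n_steps)
  if (length(D) == 0 || length(dt) == 0 || length(diameter) == 0) {
    abort("The simulation grid must contain at least one D, dt and diameter.")
  }
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All simulation parameters must be finite and strictly positive.")
  }
  structure(
    list(
      D = as.numeric(D), dt = as.numeric(dt),
      diameter = as.numeric(diameter),
      n_trajectories = as.integer(n_trajectories),
      n_steps = as.integer(n_steps),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  D (um^2/s):   ", paste(x$D, collapse = ", "), "\n")
  cat("  dt (s):       ", paste(x$dt, collapse = ", "), "\n")
  cat("  diameter (um):", paste(x$diameter, collapse = ", "), "\n")
  cat("  ", x$n_trajectories, "trajectories x", x$n_steps, "steps, seed",
      x$seed, "\n")
  invisible(x)
}

# Deterministic per-trajectory child seed. Keeps every trajectory a pure
# function of (master seed, cell index, trajectory index) so grid cells can
# be regenerated independently. All arithmetic stays below 2^31 - 1.
child_seed <- function(seed, cell, traj) {
  as.integer((as.numeric(seed) + 100003 * cell + 7919 * traj) %% 2147483647)
}

#' Simulate matched planar/cylindrical/projected trajectory triplets
#'
#' For each `(D, dt, diameter)` cell of the configuration grid, simulates
#' `n_trajectories` planar walks and derives, from the *same* underlying
#' walk, its cylindrical envelope and planar projection. Diffusion analysis
#' on the three geometries is therefore paired, which removes walk-to-walk
#' Monte Carlo variance from geometry comparisons.
#'
#' Reproducibility: each trajectory uses an independent seed derived
#' deterministically from `(config$seed, cell index, trajectory index)`
#' (a fixed linear hash into `[0, 2^31 - 1)` feeding R's default
#' Mersenne-Twister), so the output is bit-identical across runs for a
#' fixed configuration.
#'
#' @param config A [simulation_config()].
#' @return A tibble in long localization format with columns
#'   `D_sim`, `dt_s`, `diameter_um`, `trajectory_id`, `geometry`
#'   (`"planar"`, `"cylinder"`, `"projected"`), `frame`, `t_s`, `x_um`,
#'   `y_um`, `z_um` (`NA` for 2D geometries), `theta` (`NA` except on the
#'   cylinder).
#' @export
simulate_triplet_ensemble <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- tidyr::expand_grid(
    D_sim = config$D, dt_s = config$dt, diameter_um = config$diameter
  )
  grid$cell <- seq_len(nrow(grid))
  purrr::pmap_dfr(grid, function(D_sim, dt_s, diameter_um, cell) {
    purrr::map_dfr(seq_len(config$n_trajectories), function(k) {
      triplet_tbl(
        simulate_triplet(D_sim, dt_s, diameter_um, config$n_steps,
                         seed = child_seed(config$seed, cell, k)),
        D_sim, dt_s, diameter_um, k
      )
    })
  })
}

# One matched triplet as a list of three tibbles; initial angle drawn
# first so the increment stream is aligned across geometries.
simulate_triplet <- function(D, dt, diameter, n_steps, seed) {
  set.seed(seed)
  theta0 <- stats::runif(1, 0, 2 * pi)
  planar <- simulate_planar_trajectory(D, dt, n_steps)
  cyl <- wrap_on_cylinder(planar, diameter, initial_angle = theta0)
  list(planar = planar, cylinder = cyl, projected = project_to_plane(cyl))
}

triplet_tbl <- function(tri, D_sim, dt_s, diameter_um, k) {
  dplyr::bind_rows(
    dplyr::mutate(tri$planar, geometry = "planar", z_um = NA_real_,
                  theta = NA_real_),
    dplyr::mutate(tri$cylinder, geometry = "cylinder",
                  diameter_um = NULL),
    dplyr::mutate(tri$projected, geometry = "projected", z_um = NA_real_,
                  theta = NA_real_)
  ) |>
    dplyr::mutate(
      D_sim = D_sim, dt_s = dt_s, diameter_um = diameter_um,
      trajectory_id = k
    ) |>
    dplyr::select("D_sim", "dt_s", "diameter_um", "trajectory_id",
                  "geometry", "frame", "t_s", "x_um", "y_um", "z_um",
                  "theta")
}

check_trajectory_cols <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("Trajectory data is missing required column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  invisible(df)
}
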