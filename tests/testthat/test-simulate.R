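test_that("zero diffusivity pins the walk at the origin", {
  traj <- simulate_planar_trajectory(D = 0, dt = 0.015, n_steps = 100,
                                     seed = 1)
  expect_equal(nrow(traj), 101)
  expect_true(all(traj$x_um == 0) && all(traj$y_um == 0))
})

test_that("step increments have variance 2*D*dt", {
  traj <- simulate_planar_trajectory(D = 1, dt = 0.015, n_steps = 1e5,
                                     seed = 2)
  v <- var(diff(traj$x_um))
  se <- 0.03 * sqrt(2 / 1e5) # SE of a sample variance of normals
  expect_lt(abs(v - 0.030), 3 * se)
})

test_that("invalid simulation inputs are rejected with explicit messages", {
  expect_error(simulate_planar_trajectory(-1, 0.015, 10), "non-negative")
  expect_error(simulate_planar_trajectory(1, 0, 10), "positive frame interval")
  expect_error(wrap_on_cylinder(
    simulate_planar_trajectory(1, 0.015, 10, seed = 1), diameter = 0
  ), "positive cylinder diameter")
  expect_error(simulation_config(D = numeric(0)), "at least one")
})

test_that("the MSD estimator recovers its own generator's D", {
  # self-consistency oracle: D fitted on MSD points 2-5 across an
  # ensemble should centre on the simulated D
  fits <- purrr::map_dbl(1:50, function(k) {
    traj <- simulate_planar_trajectory(1, 0.015, 1000, seed = 1000 + k)
    msd <- compute_msd(traj, max_lag = 5)
    fit_diffusion(msd)$D_um2_s
  })
  expect_lt(abs(mean(fits) - 1), sd(fits))
})

test_that("cylinder wrap preserves x, satisfies the circle constraint, and unrolls isometrically", {
  p <- simulate_planar_trajectory(1, 0.015, 500, seed = 3)
  cyl <- wrap_on_cylinder(p, diameter = 0.2, initial_angle = 0.7)
  r <- 0.1
  expect_identical(cyl$x_um, p$x_um)
  expect_equal(cyl$y_um, r * cos(cyl$theta))
  expect_equal(cyl$z_um, r * sin(cyl$theta))
  expect_equal(cyl$y_um^2 + cyl$z_um^2, rep(r^2, nrow(cyl)))
  # isometry of the unrolling map, step by step at machine precision
  geodesic <- sqrt(diff(cyl$x_um)^2 + r^2 * diff(cyl$theta)^2)
  planar <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2)
  expect_equal(geodesic, planar, tolerance = 1e-12)
})

test_that("pure transverse steps wrap to the stated angles", {
  # constant-y trajectory: theta constant
  flat <- tibble::tibble(trajectory_id = 1L, frame = 0:3, t_s = (0:3) * 0.01,
                         x_um = c(0, 1, 2, 3), y_um = rep(0.4, 4))
  cyl <- wrap_on_cylinder(flat, 0.2, initial_angle = 1)
  expect_equal(cyl$theta, rep(1, 4))
  # a single step of half the circumference lands on the antipode
  half <- tibble::tibble(trajectory_id = 1L, frame = 0:1, t_s = c(0, 0.01),
                         x_um = c(0, 0), y_um = c(0, pi * 0.1))
  cyl2 <- wrap_on_cylinder(half, 0.2, initial_angle = 0.3)
  expect_equal(diff(cyl2$theta), pi)
  expect_equal(cyl2$y_um[2], -cyl2$y_um[1])
  expect_equal(cyl2$z_um[2], -cyl2$z_um[1])
})

test_that("projection drops z and is bounded by the radius", {
  p <- simulate_planar_trajectory(1, 0.015, 300, seed = 4)
  for (theta0 in c(0, pi / 2)) {
    cyl <- wrap_on_cylinder(
      dplyr::mutate(p, y_um = 0), # pinned at the initial angle
      diameter = 0.2, initial_angle = theta0
    )
    proj <- project_to_plane(cyl)
    expect_equal(proj$y_um, rep(0.1 * cos(theta0), nrow(proj)))
  }
  proj <- project_to_plane(wrap_on_cylinder(p, 0.2))
  expect_true(all(abs(proj$y_um) <= 0.1 + 1e-12))
})

test_that("triplet ensembles are deterministic and correctly shaped", {
  cfg <- simulation_config(D = 1, dt = 0.015, diameter = 0.2,
                           n_trajectories = 2, n_steps = 100, seed = 11)
  a <- simulate_triplet_ensemble(cfg)
  b <- simulate_triplet_ensemble(cfg)
  expect_identical(a, b)
  expect_equal(dplyr::n_distinct(a$trajectory_id), 2)
  expect_setequal(unique(a$geometry), c("planar", "cylinder", "projected"))
  expect_equal(nrow(a), 2 * 3 * 101)
  # x series identical across the three members of every triplet
  wide <- tidyr::pivot_wider(a, id_cols = c("trajectory_id", "frame"),
                             names_from = "geometry", values_from = "x_um")
  expect_identical(wide$planar, wide$cylinder)
  expect_identical(wide$planar, wide$projected)
})

test_that("the paper-scale cell yields 50 triplets of 1001 points", {
  cfg <- simulation_config(D = 1, dt = 0.015, diameter = 0.2,
                           n_trajectories = 50, n_steps = 1000, seed = 5)
  ens <- simulate_triplet_ensemble(cfg)
  counts <- dplyr::count(ens, trajectory_id, geometry)
  expect_equal(nrow(counts), 150)
  expect_true(all(counts$n == 1001))
})
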