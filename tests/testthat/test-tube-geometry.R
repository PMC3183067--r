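test_that("the tube projection profile is the normalized arcsine density", {
  for (dia in c(0.05, 0.2, 1)) {
    q <- integrate(tube_projection_profile, -dia / 2, dia / 2,
                   diameter = dia, rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  # centre value 2/(pi*diameter); 0.2 um -> 3.1831 um^-1
  expect_equal(tube_projection_profile(0, 0.2), 2 / (pi * 0.2),
               tolerance = 1e-12)
  expect_equal(tube_projection_profile(0, 0.2), 3.1831, tolerance = 1e-4)
  # symmetric about y_c, minimal at the centre, rising toward the edges
  y <- seq(-0.099, 0.099, length.out = 199)
  d <- tube_projection_profile(y, 0.2, y_c = 0)
  expect_equal(d, rev(d))
  expect_true(which.min(d) == 100)
  expect_true(all(diff(d[100:199]) > 0))
  expect_equal(tube_projection_profile(c(-0.11, 0.11), 0.2), c(0, 0))
})

test_that("the Gaussian profile has unit area, stated peak and variance", {
  w <- 0.045
  expect_equal(integrate(gaussian_profile, -Inf, Inf, w = w)$value, 1,
               tolerance = 1e-8)
  expect_equal(gaussian_profile(0, w), 1 / (w * sqrt(2 * pi)))
  m2 <- integrate(function(y) y^2 * gaussian_profile(y, w), -Inf, Inf)$value
  expect_equal(m2, w^2, tolerance = 1e-8)
})

test_that("the convolved profile is a proper density with variance dia^2/8 + w^2", {
  grid <- tidyr::expand_grid(dia = c(0.1, 0.225, 0.5), w = c(0.01, 0.045, 0.1))
  for (i in seq_len(nrow(grid))) {
    dia <- grid$dia[i]; w <- grid$w[i]
    lim <- dia / 2 + 8 * w
    area <- integrate(convolved_profile, -lim, lim, diameter = dia, w = w,
                      rel.tol = 1e-9)$value
    expect_equal(area, 1, tolerance = 1e-6)
    m2 <- integrate(function(y) y^2 * convolved_profile(y, dia, w),
                    -lim, lim, rel.tol = 1e-9)$value
    expect_equal(m2, dia^2 / 8 + w^2, tolerance = 0.005)
  }
  expect_true(all(convolved_profile(seq(-1, 1, 0.01), 0.2, 0.05) >= 0))
})

test_that("convolution limits recover the pure profiles", {
  y <- seq(-0.06, 0.06, length.out = 33)
  # w -> 0 converges pointwise to the arcsine profile away from the edges
  expect_equal(convolved_profile(y, 0.2, 0.002, n_nodes = 513),
               tube_projection_profile(y, 0.2), tolerance = 5e-3)
  expect_identical(convolved_profile(y, 0.2, 0),
                   tube_projection_profile(y, 0.2))
  # diameter -> 0 converges to the Gaussian
  expect_equal(convolved_profile(y, 1e-5, 0.045),
               gaussian_profile(y, 0.045), tolerance = 1e-4)
})

test_that("quadrature is stable under node refinement", {
  y <- seq(-0.2, 0.2, length.out = 81)
  c129 <- convolved_profile(y, 0.225, 0.045, n_nodes = 129)
  c513 <- convolved_profile(y, 0.225, 0.045, n_nodes = 513)
  expect_lt(max(abs(c129 - c513)), 1e-6)
})

test_that("transverse-profile fitting recovers known tube parameters", {
  # noise-free arcsine sample: diameter within 2%
  cloud0 <- make_tube_cloud(1e5, diameter = 0.3, w = 0, seed = 41)
  fit0 <- fit_transverse_distribution(cloud0, axis_model(0))
  expect_equal(fit0$diameter_um, 0.3, tolerance = 0.02)
  # smeared tube at realistic scale: 225 nm diameter, 45 nm smearing,
  # 1e4 points, recovered within +/-10 nm and +/-6 nm
  cloud <- make_tube_cloud(1e4, diameter = 0.225, w = 0.045, seed = 42)
  fit <- fit_transverse_distribution(cloud)
  expect_lt(abs(fit$diameter_um - 0.225), 0.010)
  expect_lt(abs(fit$w_um - 0.045), 0.006)
  expect_true(all(tidy(fit)$std.error >= 0, na.rm = TRUE))
  expect_true(glance(fit)$converged)
})

test_that("the likelihood objective agrees with the histogram fit", {
  cloud <- make_tube_cloud(1e4, diameter = 0.225, w = 0.045, seed = 43)
  ls <- fit_transverse_distribution(cloud, objective = "ls")
  ml <- fit_transverse_distribution(cloud, objective = "ml")
  expect_equal(ml$diameter_um, ls$diameter_um, tolerance = 0.05)
  expect_equal(ml$w_um, ls$w_um, tolerance = 0.15)
})

test_that("profile fitting is equivariant under cloud rotation", {
  cloud <- make_tube_cloud(8000, diameter = 0.225, w = 0.045, seed = 44)
  rot <- make_tube_cloud(8000, diameter = 0.225, w = 0.045,
                         angle = pi / 5, seed = 44)
  f0 <- fit_transverse_distribution(cloud)
  fr <- fit_transverse_distribution(rot)
  expect_equal(fr$diameter_um, f0$diameter_um, tolerance = 0.01)
  expect_equal(fr$w_um, f0$w_um, tolerance = 0.01)
})

test_that("sparse clouds are refused with the documented threshold", {
  tiny <- make_tube_cloud(100, diameter = 0.3, w = 0.02, seed = 45)
  expect_error(fit_transverse_distribution(tiny), "at least 2000")
})

test_that("the transversal MSD plateau reads back the diameter", {
  msd_t <- purrr::map_dfr(1:20, function(k) {
    set.seed(5000 + k)
    theta0 <- runif(1, 0, 2 * pi)
    p <- simulate_planar_trajectory(1, 0.015, 1000, particle_id = k)
    proj <- project_to_plane(wrap_on_cylinder(p, 0.2, initial_angle = theta0))
    dplyr::mutate(compute_msd_1d(proj$y_um, 0.015, max_lag = 150),
                  trajectory_id = k)
  }) |>
    ensemble_msd()
  est <- diameter_from_transverse_msd(msd_t)
  expect_equal(est$diameter_um, 0.2, tolerance = 0.05)
  expect_equal(est$plateau_um2, 0.01, tolerance = 0.1)
  # a still-rising (free 1D diffusion) curve is rejected
  free <- compute_msd_1d(simulate_planar_trajectory(1, 0.015, 2000,
                                                    seed = 46)$x_um,
                         0.015, max_lag = 100)
  expect_error(diameter_from_transverse_msd(free), "still rising")
  # a zero plateau gives a zero diameter
  flat <- tibble::tibble(lag = 1:30, lag_s = (1:30) * 0.015,
                         msd_um2 = rep(0, 30))
  expect_equal(diameter_from_transverse_msd(flat)$diameter_um, 0)
})

test_that("plateau diameters exceed profile-fit diameters on noisy data", {
  # localization noise inflates the plateau but is fitted out by the
  # smearing parameter in the profile fit
  spec <- fixture_spec(D = 0.5, diameter = 0.2, dt = 0.015,
                       n_trajectories = 20, n_frames = 1000,
                       xy_noise_um = 0.02, blink_prob = 0, seed = 47)
  ds <- generate_tube_dataset(spec)
  msd_t <- ds$trajectories |>
    dplyr::group_by(trajectory_id) |>
    dplyr::group_modify(~ compute_msd_1d(.x$y_um, spec$dt, max_lag = 150)) |>
    dplyr::ungroup() |>
    ensemble_msd()
  d_plateau <- diameter_from_transverse_msd(msd_t)$diameter_um
  fit <- fit_transverse_distribution(ds$trajectories, axis_model(0))
  expect_gte(d_plateau, fit$diameter_um)
  expect_equal(fit$diameter_um, 0.2, tolerance = 0.1)
})

test_that("envelope widths measure the diameter station by station", {
  # exact rectangle: transverse range [-0.1, 0.1] at every station
  n <- 800
  cloud <- tibble::tibble(
    x_um = rep(seq(0, 4, length.out = n / 4), 4),
    y_um = rep(c(-0.1, -0.05, 0.05, 0.1), each = n / 4)
  )
  est <- diameter_from_envelope(cloud, axis_model(0), probs = c(0, 1))
  expect_equal(est$diameter_um, 0.2, tolerance = 1e-12)
  expect_equal(est$sd_um, 0)
  # synthetic noisy tube within 15% of truth
  noisy <- make_tube_cloud(6000, diameter = 0.3, w = 0.01, seed = 48)
  est2 <- diameter_from_envelope(noisy)
  expect_equal(est2$diameter_um, 0.3, tolerance = 0.15)
  # fewer than 4 stations is refused
  expect_error(diameter_from_envelope(cloud, axis_model(0), n_stations = 3),
               "at least 4")
})

test_that("mechanical diameters follow f/(2 pi sigma)", {
  expect_equal(diameter_from_mechanics(0, 1e-5), 0)
  expect_equal(diameter_from_mechanics(1.2566e-11, 1e-5), 0.2,
               tolerance = 1e-4)
  sig <- c(1e-6, 4e-5) # typical membrane tensions
  expect_true(all(diameter_from_mechanics(5e-12, sig) > 0))
  expect_error(diameter_from_mechanics(1e-12, 0), "positive")
})
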