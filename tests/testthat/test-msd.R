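make_traj <- function(x, y, dt = 1) {
  n <- length(x)
  tibble::tibble(trajectory_id = 1L, frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
                 x_um = x, y_um = y)
}

test_that("time-averaged MSD matches hand evaluation", {
  # x = 0,1,2,3; y = 0; dt = 1 -> MSD = 1, 4, 9 at lags 1-3
  msd <- compute_msd(make_traj(c(0, 1, 2, 3), rep(0, 4)), max_lag = 3)
  expect_equal(msd$msd_um2, c(1, 4, 9))
  expect_equal(msd$n_pairs, c(3, 2, 1))
  expect_equal(msd$lag_s, c(1, 2, 3))
  # a stationary trajectory has zero MSD at all lags
  msd0 <- compute_msd(make_traj(rep(2, 10), rep(-1, 10)), max_lag = 4)
  expect_true(all(msd0$msd_um2 == 0))
})

test_that("ensemble-mean planar MSD grows as 4*D*n*dt", {
  msd <- purrr::map_dfr(1:30, function(k) {
    compute_msd(simulate_planar_trajectory(1, 0.015, 1000, seed = 100 + k),
                max_lag = 5)
  }, .id = "trajectory_id") |>
    ensemble_msd()
  expect_equal(msd$msd_um2, 4 * 1 * msd$lag_s,
               tolerance = 0.05)
})

test_that("1D MSD of deterministic drift is (v n dt)^2", {
  v <- 0.3; dt <- 0.05
  series <- (0:49) * v * dt
  msd <- compute_msd_1d(series, dt, max_lag = 8)
  expect_equal(msd$msd_um2, (v * msd$lag * dt)^2)
})

test_that("blinking gaps contribute pairs at their true frame lag", {
  # frames 0,1,2,4,5 of a unit-speed drift in x: lag-1 pairs skip the gap
  traj <- make_traj(c(0, 1, 2, 4, 5), rep(0, 5))[c(1, 2, 3, 4, 5), ]
  traj$frame <- c(0L, 1L, 2L, 4L, 5L)
  traj$t_s <- traj$frame * 1
  msd <- compute_msd(traj, max_lag = 2)
  expect_equal(msd$n_pairs, c(3, 2))
  expect_equal(msd$msd_um2, c(1, 4))
})

test_that("xyz MSD dominates xy MSD on cylindrical trajectories", {
  p <- simulate_planar_trajectory(0.5, 0.015, 500, seed = 9)
  cyl <- wrap_on_cylinder(p, 0.1)
  m3 <- compute_msd(cyl, max_lag = 10, coords = "xyz")
  m2 <- compute_msd(cyl, max_lag = 10, coords = "xy")
  expect_true(all(m3$msd_um2 >= m2$msd_um2))
  expect_true(all(m3$msd_um2 >= 0))
})

test_that("diffusion fits recover exact lines and classify mobility", {
  lag <- 1:6
  line2 <- tibble::tibble(lag = lag, lag_s = lag * 0.01,
                          msd_um2 = 4 * 0.3 * lag * 0.01 + 0.01,
                          dim_label = "2D")
  f2 <- fit_diffusion(line2)
  expect_equal(f2$D_um2_s, 0.3, tolerance = 1e-10)
  expect_equal(f2$b_um2, 0.01, tolerance = 1e-10)
  line1 <- tibble::tibble(lag = lag, lag_s = lag * 0.01,
                          msd_um2 = 2 * 0.05 * lag * 0.01 - 0.002,
                          dim_label = "1D")
  f1 <- fit_diffusion(line1, dimensionality = 1)
  expect_equal(f1$D_um2_s, 0.05, tolerance = 1e-10)
  expect_equal(f1$b_um2, -0.002, tolerance = 1e-10)
  # D below 1e-4 um^2/s is immobile
  slow <- tibble::tibble(lag = lag, lag_s = lag * 0.01,
                         msd_um2 = 4 * 5e-5 * lag * 0.01, dim_label = "2D")
  expect_equal(fit_diffusion(slow)$mobility, "immobile")
  expect_equal(f2$mobility, "mobile")
  # fit range exceeding the curve is rejected
  expect_error(fit_diffusion(line2[1:3, ]), "fewer lags")
})

test_that("tidy and glance summarise diffusion fits", {
  fits <- purrr::map_dfr(1:5, function(k) {
    traj <- simulate_planar_trajectory(0.2, 0.02, 200, seed = k,
                                       particle_id = k)
    fit_diffusion(compute_msd(traj, max_lag = 5))
  })
  class(fits) <- unique(c("diffusion_fit", class(fits)))
  g <- glance(fits)
  expect_equal(g$n_trajectories, 5)
  expect_true(g$mean_D_um2_s > 0)
  expect_s3_class(tidy(fits), "tbl_df")
})

test_that("short trajectories are filtered with an inclusive threshold", {
  traj <- dplyr::bind_rows(
    simulate_planar_trajectory(0.1, 0.01, 98, seed = 1, particle_id = 1), # 99 pts
    simulate_planar_trajectory(0.1, 0.01, 29, seed = 2, particle_id = 2), # 30 pts
    simulate_planar_trajectory(0.1, 0.01, 120, seed = 3, particle_id = 3)
  )
  kept100 <- filter_trajectories(traj, 100)
  expect_setequal(unique(kept100$trajectory_id), 3)
  kept30 <- filter_trajectories(traj, 30)
  expect_setequal(unique(kept30$trajectory_id), c(1, 2, 3))
  empty <- traj[0, ]
  expect_equal(nrow(filter_trajectories(empty, 10)), 0)
})

test_that("the survey fit kernel matches the tidy MSD + fit pathway", {
  p <- simulate_planar_trajectory(0.7, 0.02, 400, seed = 21)
  D_tidy <- fit_diffusion(compute_msd(p, max_lag = 5))$D_um2_s
  D_quick <- tubediff:::fit_D_quick(cbind(p$x_um, p$y_um), 0.02)
  expect_equal(D_quick, D_tidy, tolerance = 1e-12)
})
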