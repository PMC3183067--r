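# Shared in-code fixtures. Everything is generated at test time from
# fixed seeds; no files.

# Localization cloud of a straight tube: uniform along the axis, arcsine
# transverse profile (uniform angle around the cylinder) plus Gaussian
# smearing, rotated into the image plane.
make_tube_cloud <- function(n, diameter, w = 0, y_c = 0, angle = 0,
                            length_um = 5, seed = 1) {
  set.seed(seed)
  long <- runif(n, 0, length_um)
  transv <- y_c + (diameter / 2) * cos(runif(n, 0, 2 * pi))
  if (w > 0) transv <- transv + rnorm(n, 0, w)
  tibble::tibble(
    x_um = cos(angle) * long - sin(angle) * transv,
    y_um = sin(angle) * long + cos(angle) * transv
  )
}

# Synthetic astigmatism defocus model: spot widths from a quadratic
# defocus curve with foci offset +/- c_nm, the standard cylindrical-lens
# picture. Monotone wx/wy over a limited central range.
defocus_widths <- function(z_nm, w0 = 1.3, d_nm = 400, c_nm = 200) {
  wx <- w0 * sqrt(1 + ((z_nm - c_nm) / d_nm)^2)
  wy <- w0 * sqrt(1 + ((z_nm + c_nm) / d_nm)^2)
  tibble::tibble(z_nm = z_nm, wx = wx, wy = wy)
}

# Mean bias ratios for one simulation cell (wrapper used by several
# test files and by the acceptance suite).
bias_cell <- function(D, dt, diameter, seed, n_trajectories = 50,
                      n_steps = 1000) {
  build_bias_table(simulation_config(
    D = D, dt = dt, diameter = diameter,
    n_trajectories = n_trajectories, n_steps = n_steps, seed = seed
  ))
}
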