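#' Dimensionless curvature-bias parameter
#'
#' The squared ratio of the RMS in-plane distance a particle travels
#' between two consecutive acquisitions, `sqrt(4*D*dt)`, to the cylinder
#' diameter:
#'
#' \deqn{\epsilon = 4 D \, dt / \O^2}
#'
#' Small `epsilon` means steps are short relative to the tube
#' circumference, so only the projection itself biases the measurement;
#' large `epsilon` means consecutive points wind around the tube between
#' frames and transverse displacements carry almost no information.
#' `epsilon` alone predicts the mean ratio of measured to true D
#' (see [predicted_ratio()]): conditions with equal `epsilon` but
#' different `(D, dt, diameter)` collapse onto one master curve.
#'
#' @param D True (or estimated) diffusion coefficient (um^2/s), `> 0`.
#' @param dt Frame interval (s), `> 0`.
#' @param diameter Tube diameter (um), `> 0`.
#' @return Dimensionless `epsilon` (vectorized over the inputs).
#' @examples
#' epsilon_parameter(D = 1, dt = 0.015, diameter = 0.1) # 6
#' @export
epsilon_parameter <- function(D, dt, diameter) {
  if (any(!is.finite(D)) || any(D <= 0) ||
      any(!is.finite(dt)) || any(dt <= 0) ||
      any(!is.finite(diameter)) || any(diameter <= 0)) {
    abort("`D`, `dt` and `diameter` must all be finite and strictly positive.")
  }
  4 * D * dt / diameter^2
}

# Lean per-trajectory MSD fit used by the grid survey; numerically
# identical to compute_msd() + fit_diffusion() (asserted in the tests)
# but avoids per-trajectory tibble construction on 10^4-cell grids.
fit_D_quick <- function(pos, dt, dim_fit = 2L, fit_points = 2:5) {
  n <- nrow(pos)
  m <- vapply(fit_points, function(l) {
    d <- pos[(l + 1):n, , drop = FALSE] - pos[1:(n - l), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  t <- fit_points * dt
  slope <- stats::cov(t, m) / stats::var(t)
  slope / (2 * dim_fit)
}

#' Survey the geometric bias over a simulation grid
#'
#' Runs the matched-triplet Monte Carlo over every `(D, dt, diameter)`
#' cell of `config`, fits D on MSD points `2:5` in the three geometries
#' (planar with `4Dt+b`; cylindrical from the 3D coordinates, also with
#' `4Dt+b` since diffusion occurs on a 2D surface; projected with
#' `4Dt+b`), and aggregates per-trajectory ratios within each cell.
#'
#' @param config A [simulation_config()]; the default grid spans the
#'   usual SPT regimes (D 0.001-1 um^2/s, dt 5-100 ms, diameters
#'   50-5000 nm, 50 trajectories x 1000 steps per cell).
#' @param fit_points Integer lags used in each fit (default `2:5`).
#' @return A tibble of class `bias_table`: one row per grid cell with
#'   `D_sim`, `dt_s`, `diameter_um`, `epsilon`, the mean and SD over
#'   trajectories of `ratio_cyl` (`D_cyl/D_actual`), `ratio_proj`
#'   (`D_proj/D_actual`) and `ratio_proj_cyl` (`D_proj/D_cyl`), and `n`.
#'   The generating configuration is attached as attribute `config`.
#' @export
build_bias_table <- function(config = simulation_config(), fit_points = 2:5) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_steps <= max(fit_points)) {
    abort("`n_steps` must exceed the largest fit lag.")
  }
  grid <- tidyr::expand_grid(
    D_sim = config$D, dt_s = config$dt, diameter_um = config$diameter
  )
  grid$cell <- seq_len(nrow(grid))
  out <- purrr::pmap_dfr(grid, function(D_sim, dt_s, diameter_um, cell) {
    rc <- rp <- rpc <- numeric(config$n_trajectories)
    for (k in seq_len(config$n_trajectories)) {
      tri <- simulate_triplet(D_sim, dt_s, diameter_um, config$n_steps,
                              seed = child_seed(config$seed, cell, k))
      Da <- fit_D_quick(cbind(tri$planar$x_um, tri$planar$y_um), dt_s,
                        2L, fit_points)
      Dc <- fit_D_quick(cbind(tri$cylinder$x_um, tri$cylinder$y_um,
                              tri$cylinder$z_um), dt_s, 2L, fit_points)
      Dp <- fit_D_quick(cbind(tri$projected$x_um, tri$projected$y_um),
                        dt_s, 2L, fit_points)
      rc[k] <- Dc / Da; rp[k] <- Dp / Da; rpc[k] <- Dp / Dc
    }
    tibble::tibble(
      D_sim = D_sim, dt_s = dt_s, diameter_um = diameter_um,
      epsilon = epsilon_parameter(D_sim, dt_s, diameter_um),
      mean_ratio_cyl = mean(rc), sd_ratio_cyl = stats::sd(rc),
      mean_ratio_proj = mean(rp), sd_ratio_proj = stats::sd(rp),
      mean_ratio_proj_cyl = mean(rpc), sd_ratio_proj_cyl = stats::sd(rpc),
      n = config$n_trajectories
    )
  })
  attr(out, "config") <- config
  class(out) <- unique(c("bias_table", class(out)))
  out
}

#' Write / read a bias table as delimited text
#'
#' The table is written as TSV preceded by a JSON metadata header (lines
#' prefixed with `#`) recording the generating configuration and seed, so
#' any persisted table can be regenerated exactly.
#'
#' @param x A `bias_table` from [build_bias_table()].
#' @param path Output/input file path.
#' @return `write_bias_table()` returns `path` invisibly;
#'   `read_bias_table()` returns the `bias_table` tibble with the parsed
#'   configuration reattached.
#' @export
write_bias_table <- function(x, path) {
  stopifnot(inherits(x, "bias_table"))
  cfg <- attr(x, "config")
  meta <- jsonlite::toJSON(
    list(
      format = "tubediff bias_table",
      version = as.character(utils::packageVersion("tubediff")),
      config = unclass(cfg)
    ),
    auto_unbox = TRUE, digits = NA
  )
  header <- paste0("# ", strsplit(as.character(meta), "\n")[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- jsonlite::fromJSON(paste(sub("^# ?", "", lines[hdr]), collapse = ""))
  tbl <- utils::read.table(text = lines[!hdr], header = TRUE, sep = "\t")
  tbl <- tibble::as_tibble(tbl)
  if (!is.null(meta$config)) {
    attr(tbl, "config") <- do.call(simulation_config, meta$config)
  }
  class(tbl) <- unique(c("bias_table", class(tbl)))
  tbl
}

# Cached bundled master table (shipped in inst/extdata with its seed and
# configuration; regenerate with build_bias_table on the recorded config).
.tubediff_cache <- new.env(parent = emptyenv())

bias_master <- function() {
  if (is.null(.tubediff_cache$master)) {
    path <- system.file("extdata", "bias_master.tsv", package = "tubediff")
    if (!nzchar(path)) abort("Bundled bias master table not found.")
    .tubediff_cache$master <- read_bias_table(path)
  }
  .tubediff_cache$master
}

# Binned, monotone master curve: geometric bins in epsilon (20 per
# decade), bin-mean ratios, then an isotone (non-increasing) fit so that
# interpolation never inverts the physical ordering.
master_curve <- function(mode = c("projected", "cylindrical"),
                         table = NULL, bins_per_decade = 20) {
  mode <- match.arg(mode)
  tbl <- table %||% bias_master()
  col <- if (mode == "projected") "mean_ratio_proj" else "mean_ratio_cyl"
  sdc <- if (mode == "projected") "sd_ratio_proj" else "sd_ratio_cyl"
  le <- log10(tbl$epsilon)
  bin <- floor(le * bins_per_decade)
  agg <- tibble::tibble(le = le, r = tbl[[col]], s = tbl[[sdc]], bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      le = mean(.data$le),
      r = mean(.data$r),
      s = sqrt(mean(.data$s^2)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$le)
  iso <- stats::isoreg(agg$le, -agg$r)
  agg$r_mono <- -iso$yf
  agg
}

#' Predicted ratio of measured to true diffusion coefficient
#'
#' Interpolates the simulation-derived master curve of the mean bias
#' ratio against the dimensionless parameter `epsilon` (see
#' [epsilon_parameter()]). `mode = "projected"` gives `D_proj/D_actual`
#' (2D SPT on a tube); `mode = "cylindrical"` gives `D_cyl/D_actual`
#' (3D SPT). As `epsilon -> 0` the projected ratio approaches 0.75 and
#' the cylindrical ratio approaches 1; for large `epsilon` both fall
#' toward 0.5, the longitudinal-only limit.
#'
#' Values of `epsilon` outside the simulated range are clamped to the
#' nearest asymptote with a warning, not extrapolated.
#'
#' @param epsilon Dimensionless bias parameter (vectorized).
#' @param mode `"projected"` or `"cylindrical"`.
#' @param table Optional `bias_table` to use instead of the bundled
#'   master (e.g. one regenerated with a different grid).
#' @return Numeric vector of predicted ratios in `(0, 1]`.
#' @export
predicted_ratio <- function(epsilon, mode = c("projected", "cylindrical"),
                            table = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    abort("`epsilon` must be finite and strictly positive.")
  }
  crv <- master_curve(mode, table)
  le <- log10(epsilon)
  if (any(le < min(crv$le)) || any(le > max(crv$le))) {
    warn(paste0(
      "epsilon outside the simulated range [",
      signif(10^min(crv$le), 3), ", ", signif(10^max(crv$le), 3),
      "]; clamping to the nearest asymptote."
    ))
  }
  stats::approx(crv$le, crv$r_mono, xout = le, rule = 2)$y
}

#' Correct a measured diffusion coefficient for tube-curvature bias
#'
#' Inverts the master bias curve to recover the true diffusion
#' coefficient from one measured on a tube of known diameter. Because
#' `epsilon` depends on the unknown true D, the inversion is a fixed
#' point: `D* = D_measured / ratio(epsilon(D*, dt, diameter))`, iterated
#' from `D_measured` to a relative tolerance of `1e-6`.
#'
#' The uncertainty band propagates the across-trajectory SD of the bias
#' ratio at the solution's `epsilon` through the correction.
#'
#' @param D_measured Measured diffusion coefficient (um^2/s), `> 0`.
#' @param dt Frame interval (s).
#' @param diameter Tube diameter (um).
#' @param mode `"projected"` (2D SPT) or `"cylindrical"` (3D SPT).
#' @param table Optional `bias_table` overriding the bundled master.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return A one-row tibble: `D_corrected`, `D_lo`, `D_hi` (band),
#'   `epsilon` and `ratio` at the solution, `iterations`, `converged`.
#' @export
correct_diffusivity <- function(D_measured, dt, diameter,
                                mode = c("projected", "cylindrical"),
                                table = NULL, max_iter = 100, tol = 1e-6) {
  mode <- match.arg(mode)
  if (!is.finite(D_measured) || D_measured <= 0) {
    abort("`D_measured` must be finite and strictly positive.")
  }
  crv <- master_curve(mode, table)
  ratio_at <- function(D) {
    le <- pmin(pmax(log10(epsilon_parameter(D, dt, diameter)), min(crv$le)),
               max(crv$le))
    stats::approx(crv$le, crv$r_mono, xout = le, rule = 2)$y
  }
  D <- D_measured
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    D_new <- D_measured / ratio_at(D)
    if (abs(D_new - D) <= tol * D) {
      D <- D_new
      converged <- TRUE
      break
    }
    D <- D_new
  }
  if (!converged) {
    abort(sprintf(
      "Bias correction did not converge in %d iterations (last iterate %.6g um^2/s).",
      max_iter, D
    ))
  }
  eps <- epsilon_parameter(D, dt, diameter)
  le <- pmin(pmax(log10(eps), min(crv$le)), max(crv$le))
  r <- stats::approx(crv$le, crv$r_mono, xout = le, rule = 2)$y
  s <- stats::approx(crv$le, crv$s, xout = le, rule = 2)$y
  tibble::tibble(
    D_corrected = D,
    D_lo = D_measured / (r + s),
    D_hi = D_measured / max(r - s, .Machine$double.eps),
    epsilon = eps,
    ratio = r,
    iterations = i,
    converged = converged
  )
}
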