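#' Transverse projection profile of a uniformly labelled tube
#'
#' Probability density of the transverse coordinate obtained by projecting
#' points uniformly distributed over the surface of a straight cylinder
#' onto the imaging plane. If the transverse coordinate is
#' `y = (diameter/2) * cos(theta)` with `theta` uniform, its density is
#' the arcsine law
#'
#' \deqn{p(y) = \frac{1}{\pi \sqrt{(\O/2)^2 - (y - y_c)^2}}}
#'
#' for `|y - y_c| < diameter/2` and 0 outside. The density is symmetric
#' about `y_c`, minimal at the centre (value `2/(pi*diameter)`) and
#' diverges toward the edges: a marker is more likely to be seen near the
#' side of the tube than over its middle, because the projected position
#' changes slowly with angle near the edge.
#'
#' @param y Transverse coordinate(s) (um).
#' @param diameter Tube diameter (um), `> 0`.
#' @param y_c Tube centre (um).
#' @return Density values (um^-1), vectorized over `y`.
#' @export
tube_projection_profile <- function(y, diameter, y_c = 0) {
  if (!is.finite(diameter) || diameter <= 0) {
    abort("`diameter` must be strictly positive.")
  }
  r <- diameter / 2
  u <- y - y_c
  out <- numeric(length(y))
  inside <- abs(u) < r
  out[inside] <- 1 / (pi * sqrt(r^2 - u[inside]^2))
  out
}

#' Gaussian smearing profile
#'
#' Unit-area Gaussian density with standard deviation `w` centred at 0,
#' modelling the combined blur from finite localization accuracy, tube
#' shape fluctuations and drift of the tube position.
#'
#' @param y Coordinate(s) (um).
#' @param w Smearing width = standard deviation (um), `> 0`.
#' @return Density values (um^-1).
#' @export
gaussian_profile <- function(y, w) {
  if (!is.finite(w) || w <= 0) abort("`w` must be strictly positive.")
  stats::dnorm(y, mean = 0, sd = w)
}

#' Convolution of the tube projection profile with a Gaussian
#'
#' The measurable transverse distribution of localizations on a tube:
#' the arcsine projection profile convolved with Gaussian smearing of
#' width `w`. The substitution `y' = y_c + (diameter/2) sin(u)` removes
#' the integrable singularities at the tube edges, giving
#'
#' \deqn{C(y) = \frac{1}{\pi} \int_{-\pi/2}^{\pi/2}
#'   G\!\big(y - y_c - (\O/2)\sin u\big)\, du}
#'
#' which is evaluated with a fixed 129-point Gauss-Legendre rule (absolute
#' accuracy better than 1e-6 um^-1 over the parameter ranges of interest;
#' checked against rule refinement in the tests). `C` is a proper density
#' with variance `diameter^2/8 + w^2` (arcsine variance plus Gaussian
#' variance), which is also how moment-matched starting values for
#' fitting are formed.
#'
#' @param y Transverse coordinate(s) (um).
#' @param diameter Tube diameter (um), `> 0`.
#' @param w Smearing width (um), `>= 0`; `w = 0` returns the unsmeared
#'   projection profile (its delta-kernel limit).
#' @param y_c Tube centre (um).
#' @param n_nodes Number of quadrature nodes (default 129).
#' @return Density values (um^-1), vectorized over `y`.
#' @export
convolved_profile <- function(y, diameter, w, y_c = 0, n_nodes = 129) {
  if (!is.finite(diameter) || diameter <= 0) {
    abort("`diameter` must be strictly positive.")
  }
  if (!is.finite(w) || w < 0) abort("`w` must be non-negative.")
  if (w == 0) return(tube_projection_profile(y, diameter, y_c))
  gl <- pracma::gaussLegendre(n_nodes, -pi / 2, pi / 2)
  # outer(): |y| x |nodes| Gaussian evaluations, then weighted row sums
  shift <- y_c + (diameter / 2) * sin(gl$x)
  G <- stats::dnorm(outer(y, shift, `-`), sd = w)
  as.numeric(G %*% gl$w) / pi
}

#' Fit the transverse localization distribution of a tube
#'
#' Estimates the tube diameter, smearing width and centre by fitting the
#' convolved profile ([convolved_profile()]) to the distribution of
#' transverse coordinates of a localization cloud. This resolves tube
#' diameters well below the optical diffraction limit, because the
#' *positions* of single emitters are known to ~10 nm even when the tube
#' image itself is a diffraction-blurred stripe.
#'
#' The default objective is least squares between the model density and a
#' density-normalized histogram (bin width `max(5 nm, Freedman-Diaconis)`);
#' `objective = "ml"` maximizes the exact likelihood of the unbinned
#' coordinates instead. Fits start from moment-matched values
#' `diameter0 = 2*sqrt(2*max(var(y) - w0^2, eps))` for several candidate
#' `w0`, and the best local optimum is kept; this avoids the
#' diameter/smearing trade-off minima. Parameter uncertainties come from
#' the local curvature of the objective at the optimum.
#'
#' Because the fit is against a stochastic distribution, a few thousand
#' localizations are required for a stable answer; below `min_points`
#' (default 2000) the fit is refused.
#'
#' @param cloud Localization tibble with columns `x_um`, `y_um`.
#' @param axis Optional [axis_model()]; when `NULL` the axis is first
#'   estimated from the cloud by total least squares.
#' @param objective `"ls"` (histogram least squares, default) or `"ml"`
#'   (maximum likelihood on unbinned coordinates).
#' @param bin_width Histogram bin width (um); default
#'   `max(0.005, Freedman-Diaconis)`.
#' @param w_starts Candidate starting smearing widths (um).
#' @param min_points Minimum number of localizations (default 2000).
#' @return An object of class `tube_fit`: estimates and standard errors
#'   for `diameter_um`, `w_um`, `y_c_um`, plus diagnostics (`objective`,
#'   `residual_norm`, `n_points`, `bin_width`, `convergence`). Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_transverse_distribution <- function(cloud, axis = NULL,
                                        objective = c("ls", "ml"),
                                        bin_width = NULL,
                                        w_starts = c(0.010, 0.050, 0.100),
                                        min_points = 2000) {
  objective <- match.arg(objective)
  check_trajectory_cols(cloud, c("x_um", "y_um"))
  if (nrow(cloud) < min_points) {
    abort(sprintf(
      "Transverse-profile fitting needs at least %d localizations (got %d); the distribution of stochastic positions is otherwise too noisy to constrain the diameter.",
      min_points, nrow(cloud)
    ))
  }
  if (is.null(axis)) axis <- estimate_axis(cloud)
  tv <- decompose_trajectory(cloud, axis)$transv_um
  tv <- tv[is.finite(tv)]

  v <- stats::var(tv)
  starts <- purrr::map(w_starts, function(w0) {
    d0 <- 2 * sqrt(2 * max(v - w0^2, 1e-6))
    c(diameter = d0, w = w0, y_c = mean(tv))
  })

  if (objective == "ls") {
    if (is.null(bin_width)) {
      fd <- 2 * stats::IQR(tv) / length(tv)^(1 / 3)
      bin_width <- max(0.005, fd)
    }
    breaks <- seq(min(tv) - bin_width, max(tv) + bin_width, by = bin_width)
    h <- graphics::hist(tv, breaks = breaks, plot = FALSE)
    resid_fn <- function(p) {
      convolved_profile(h$mids, p[1], p[2], p[3]) - h$density
    }
    fits <- purrr::map(starts, function(p0) {
      tryCatch(
        minpack.lm::nls.lm(
          par = p0, fn = resid_fn,
          lower = c(1e-4, 1e-4, min(tv)), upper = c(Inf, Inf, max(tv)),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
    })
    fits <- purrr::compact(fits)
    if (length(fits) == 0) {
      abort("Transverse-profile fit failed to converge from any starting point.")
    }
    best <- fits[[which.min(purrr::map_dbl(fits, "deviance"))]]
    p <- best$par
    # SEs from the Jacobian-based covariance, scaled by residual variance
    dof <- max(length(h$mids) - 3, 1)
    sigma2 <- best$deviance / dof
    cv <- tryCatch(sigma2 * solve(best$hessian / 2), error = function(e) NULL)
    se <- if (is.null(cv)) rep(NA_real_, 3) else sqrt(pmax(diag(cv), 0))
    res <- list(
      diameter_um = unname(p[1]), w_um = unname(p[2]), y_c_um = unname(p[3]),
      se = stats::setNames(se, c("diameter_um", "w_um", "y_c_um")),
      objective = "ls", residual_norm = sqrt(best$deviance),
      n_points = length(tv), bin_width = bin_width,
      convergence = best$info %in% 1:4,
      histogram = tibble::tibble(y_um = h$mids, density = h$density)
    )
  } else {
    nll <- function(p) {
      d <- convolved_profile(tv, p[1], p[2], p[3])
      -sum(log(pmax(d, 1e-300)))
    }
    fits <- purrr::map(starts, function(p0) {
      tryCatch(
        stats::optim(p0, nll, method = "L-BFGS-B",
                     lower = c(1e-4, 1e-4, min(tv)),
                     upper = c(Inf, Inf, max(tv)), hessian = TRUE),
        error = function(e) NULL
      )
    })
    fits <- purrr::compact(fits)
    if (length(fits) == 0) {
      abort("Transverse-profile fit failed to converge from any starting point.")
    }
    best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
    p <- best$par
    cv <- tryCatch(solve(best$hessian), error = function(e) NULL)
    se <- if (is.null(cv)) rep(NA_real_, 3) else sqrt(pmax(diag(cv), 0))
    res <- list(
      diameter_um = unname(p[1]), w_um = unname(p[2]), y_c_um = unname(p[3]),
      se = stats::setNames(se, c("diameter_um", "w_um", "y_c_um")),
      objective = "ml", residual_norm = best$value,
      n_points = length(tv), bin_width = NA_real_,
      convergence = best$convergence == 0,
      histogram = {
        bw <- max(0.005, 2 * stats::IQR(tv) / length(tv)^(1 / 3))
        brk <- seq(min(tv) - bw, max(tv) + bw, by = bw)
        h <- graphics::hist(tv, breaks = brk, plot = FALSE)
        tibble::tibble(y_um = h$mids, density = h$density)
      }
    )
  }
  res$axis <- axis
  if (!res$convergence) {
    abort(sprintf(
      "Transverse-profile fit did not converge (best objective %.4g); inspect the cloud or supply starting values.",
      res$residual_norm
    ))
  }
  structure(res, class = "tube_fit")
}

#' @export
print.tube_fit <- function(x, ...) {
  cat("<tube_fit>", x$objective, "fit of the smeared tube projection profile\n")
  cat(sprintf("  diameter: %.1f +/- %.1f nm\n",
              1000 * x$diameter_um, 1000 * x$se[["diameter_um"]]))
  cat(sprintf("  smearing w: %.1f +/- %.1f nm\n",
              1000 * x$w_um, 1000 * x$se[["w_um"]]))
  cat(sprintf("  centre y_c: %.4f um;  n = %d localizations\n",
              x$y_c_um, x$n_points))
  invisible(x)
}

#' @export
tidy.tube_fit <- function(x, ...) {
  tibble::tibble(
    term = c("diameter_um", "w_um", "y_c_um"),
    estimate = c(x$diameter_um, x$w_um, x$y_c_um),
    std.error = unname(x$se)
  )
}

#' @export
glance.tube_fit <- function(x, ...) {
  tibble::tibble(
    diameter_um = x$diameter_um,
    w_um = x$w_um,
    objective = x$objective,
    residual_norm = x$residual_norm,
    n_points = x$n_points,
    converged = x$convergence
  )
}

#' Tube diameter from the transversal MSD plateau
#'
#' On a tube, transverse displacements are confined: the transversal MSD
#' saturates at a plateau equal to twice the variance of the projected
#' transverse coordinate, `2 * (diameter/2)^2 / 2 = diameter^2 / 4`, i.e.
#' the squared tube radius. The diameter is therefore `2 * sqrt(P)` where
#' `P` is the plateau level. Smearing by localization error and tube
#' fluctuations adds to the plateau, so this estimator tends to read
#' slightly high on noisy data.
#'
#' The plateau is taken as the mean MSD over the final `tail_fraction` of
#' lags, accepted only if that stretch is flat: the fitted relative slope
#' across it must be below `max_rel_slope`.
#'
#' @param msd_transv An `msd_curve` of the transversal 1D component (one
#'   curve; average over trajectories first with [ensemble_msd()]).
#' @param tail_fraction Fraction of the largest lags used (default 1/3).
#' @param max_rel_slope Maximum allowed relative MSD change across the
#'   tail stretch (default 0.15).
#' @return A one-row tibble: `diameter_um`, `plateau_um2`, `rel_slope`,
#'   `n_lags_used`.
#' @export
diameter_from_transverse_msd <- function(msd_transv, tail_fraction = 1 / 3,
                                         max_rel_slope = 0.15) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(msd_transv)))
  crv <- dplyr::arrange(msd_transv, .data$lag_s)
  n <- nrow(crv)
  k <- max(3L, ceiling(n * tail_fraction))
  tail_crv <- crv[(n - k + 1):n, ]
  P <- mean(tail_crv$msd_um2)
  if (P < 0) abort("Transversal MSD tail is negative; not a valid plateau.")
  if (P == 0) {
    return(tibble::tibble(diameter_um = 0, plateau_um2 = 0, rel_slope = 0,
                          n_lags_used = k))
  }
  slope <- stats::coef(stats::lm(msd_um2 ~ lag_s, data = tail_crv))[["lag_s"]]
  rel_slope <- slope * diff(range(tail_crv$lag_s)) / P
  if (!is.finite(rel_slope) || rel_slope > max_rel_slope) {
    abort(paste0(
      "No transversal MSD plateau: the curve is still rising over the final ",
      "stretch (relative slope ", signif(rel_slope, 3), " > ",
      max_rel_slope, "). Longer trajectories or larger lags are needed."
    ))
  }
  tibble::tibble(
    diameter_um = 2 * sqrt(P), plateau_um2 = P,
    rel_slope = rel_slope, n_lags_used = k
  )
}

#' Tube diameter from the transverse envelope width
#'
#' Reconstructs the tube outline as a rectangle: the cloud is cut into
#' stations along the axis and the transverse width is measured at each
#' station, by default as the inner 1st-99th percentile span (robust to
#' stray localizations; `probs = c(0, 1)` gives the strict min-max
#' width). Intended for clouds too sparse for the profile fit.
#'
#' @param cloud Localization tibble with `x_um`, `y_um`.
#' @param axis Optional [axis_model()] (estimated from the cloud if
#'   `NULL`).
#' @param n_stations Number of stations along the axis (default 8; at
#'   least 4 stations with >= 2 points each are required).
#' @param probs Length-2 transverse quantile pair defining the width.
#' @return A one-row tibble: `diameter_um` (mean width over stations),
#'   `sd_um`, `n_stations`.
#' @export
diameter_from_envelope <- function(cloud, axis = NULL, n_stations = 8,
                                   probs = c(0.01, 0.99)) {
  check_trajectory_cols(cloud, c("x_um", "y_um"))
  stopifnot(length(probs) == 2, probs[1] < probs[2])
  if (is.null(axis)) axis <- estimate_axis(cloud)
  dec <- decompose_trajectory(cloud, axis)
  cuts <- cut(dec$long_um, breaks = n_stations)
  widths <- dec |>
    dplyr::mutate(station = cuts) |>
    dplyr::group_by(.data$station) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      width = diff(stats::quantile(.data$transv_um, probs, names = FALSE)),
      .groups = "drop"
    )
  if (nrow(widths) < 4) {
    abort(sprintf(
      "Envelope width needs at least 4 populated stations along the axis (got %d).",
      nrow(widths)
    ))
  }
  tibble::tibble(
    diameter_um = mean(widths$width),
    sd_um = stats::sd(widths$width),
    n_stations = nrow(widths)
  )
}

#' Tube diameter from membrane mechanics
#'
#' A membrane tether pulled from a vesicle at tension `sigma` by force
#' `f` equilibrates at diameter `f / (2*pi*sigma)`. Typical experimental
#' tensions are 1e-6 to 4e-5 N/m with forces of a few to tens of pN.
#'
#' @param f Pulling force (N), `>= 0`.
#' @param sigma Membrane tension (N/m), `> 0`.
#' @return Diameter in um (vectorized).
#' @examples
#' diameter_from_mechanics(f = 1.2566e-11, sigma = 1e-5) # ~0.2 um
#' @export
diameter_from_mechanics <- function(f, sigma) {
  if (any(!is.finite(f)) || any(f < 0)) abort("`f` must be non-negative (N).")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be strictly positive (N/m).")
  }
  1e6 * f / (2 * pi * sigma)
}
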