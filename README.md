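# tubediff

Single-particle tracking (SPT) on tubular membranes — axons, dendrites,
spine necks, pulled membrane tethers — records the *projection* of
motion on a curved surface onto the camera plane. The projection drops
the out-of-plane component of every step and measures circumferential
motion as a chord instead of an arc, so diffusion coefficients fitted
from MSD curves of projected trajectories systematically underestimate
the true surface diffusivity, by 25% up to 50% depending on conditions.

`tubediff` is for SPT practitioners who track molecules on tubes. It:

- simulates matched **planar / cylindrical / projected** trajectory
  triplets (same Brownian walk, three geometries) with a seeded,
  reproducible Monte Carlo engine;
- computes time-averaged **MSD** curves (1D / 2D / 3D-coordinate,
  blink-gap aware) and fits `MSD(t) = 4Dt + b` or `2Dt + b` on points
  2–5, with mobile/immobile classification;
- quantifies the bias as a function of a single dimensionless parameter
  **ε = 4·D·dt/Ø²** (squared RMS step over tube diameter), ships a
  simulation-derived master curve, and **corrects** measured D by
  fixed-point inversion of that curve;
- provides the unbiased estimator: D from the **longitudinal**
  (axis-parallel) displacement component, which curvature cannot touch;
- estimates **sub-diffraction tube diameters** four ways: fitting the
  transverse localization histogram with the arcsine-projection profile
  convolved with a Gaussian; the transversal-MSD plateau (= Ø²/4); the
  envelope-rectangle width; and membrane mechanics Ø = f/(2πσ);
- calibrates **astigmatism-based z-localization** (wx/wy → z) for 3D
  SPT, with strict monotone-range handling;
- generates **synthetic QD-on-tube datasets** (noise + blinking) with
  ground truth, for validation and testing.

Everything is tidyverse-native: functions take and return tibbles,
fitted objects support `tidy()`/`glance()`/`autoplot()`.

## Worked example

How badly does 2D SPT mismeasure a fast lipid on a thin tube, and what
do we get back?

```r
library(tubediff)

# One survey cell: D = 1 um^2/s, dt = 15 ms, tube diameter 100 nm,
# 50 trajectories x 1000 steps, all three geometries fitted.
bt <- build_bias_table(simulation_config(
  D = 1, dt = 0.015, diameter = 0.1,
  n_trajectories = 50, n_steps = 1000, seed = 42
))
bt[, c("epsilon", "mean_ratio_proj", "sd_ratio_proj", "mean_ratio_cyl")]
#>   epsilon mean_ratio_proj sd_ratio_proj mean_ratio_cyl
#> 1       6       0.4968893    0.04715532      0.4969004
```

ε = 6: between two frames the particle's RMS step is ~2.4× the tube
diameter. Projected 2D SPT recovers only ~50% of the true D — and the
3D-coordinate readout is just as biased, because the motion wraps the
tube several times per frame. The bundled master curve predicts the
same number without simulating:

```r
predicted_ratio(epsilon_parameter(1, 0.015, 0.1), "projected")
#> [1] 0.5012715
```

Inverting the curve corrects a measured value (here D_meas = 0.55
um^2/s on a 100 nm tube at 15 ms):

```r
correct_diffusivity(0.55, 0.015, 0.1, mode = "projected")
#> # A tibble: 1 x 7
#>   D_corrected  D_lo  D_hi epsilon ratio iterations converged
#>         <dbl> <dbl> <dbl>   <dbl> <dbl>      <int> <lgl>
#> 1        1.10  1.02  1.19    6.58 0.501          2 TRUE
```

The same data also measure the tube itself. A cloud of 10⁴
localizations on a 225 nm tube smeared by 45 nm of localization error:

```r
set.seed(9); n <- 1e4
cloud <- tibble::tibble(
  x_um = runif(n, 0, 5),
  y_um = 0.1125 * cos(runif(n, 0, 2 * pi)) + rnorm(n, 0, 0.045)
)
fit_transverse_distribution(cloud)
#> <tube_fit> ls fit of the smeared tube projection profile
#>   diameter: 223.8 +/- 2.0 nm
#>   smearing w: 44.6 +/- 1.1 nm
#>   centre y_c: 0.0009 um;  n = 10000 localizations
```

Both parameters are recovered well below the diffraction limit. For an
unbiased D regardless of diameter, fit only the axis-parallel component:
`estimate_longitudinal_D(traj, estimate_axis(traj))`.

A thin CLI over the same functions lives at `inst/cli/tubediff.R`
(subcommands `simulate`, `biasmap`, `msd`, `fitd`, `decompose`,
`tubefit`, `zcalib`, `fixtures`; every stochastic subcommand takes
`--seed`).

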