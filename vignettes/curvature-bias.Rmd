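---
title: "Diffusion measurements on tubular membranes: the geometric bias and how tubediff handles it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion measurements on tubular membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubediff)
```

## The problem

Single-particle tracking (SPT) reconstructs the path of one labelled
molecule from time-lapse localizations and reads the lateral diffusion
coefficient \(D\) off the mean squared displacement (MSD). On a flat
membrane parallel to the focal plane this is straightforward:
\(\mathrm{MSD}(t) = 4Dt + b\). But many biological membranes of interest
— axons, dendrites, the necks of dendritic spines, pulled membrane
tethers — are tubes with diameters of 50–1000 nm, far below or near the
optical resolution limit. A camera records the *projection* of motion on
the tube surface onto the image plane, and two things go wrong:

1. the out-of-plane (z) part of each displacement is lost, and
2. motion around the circumference is measured as the chord, not the arc.

Both shorten apparent displacements, so \(D\) fitted from projected
trajectories systematically underestimates the true surface diffusivity.
The size of the error depends on the tube diameter \(\O\), the frame
interval \(dt\) and the mobility \(D\) itself.

`tubediff` quantifies this bias by Monte Carlo simulation, predicts it
from a single dimensionless parameter, corrects measured diffusivities,
provides an estimator that is immune to the bias, and estimates
sub-diffraction tube diameters from the same SPT data.

## The simulation model

Trajectories are free Brownian walks on a plane: per-axis step
increments are i.i.d. normal with mean 0 and variance \(2 D\, dt\). The
planar walk is then *enveloped* on a cylinder whose axis is the x-axis:
x is kept, and each transverse displacement becomes an angular increment
\(\Delta\theta = \Delta y / (\O/2)\), i.e. planar distance becomes arc
length. Cartesian coordinates on the tube are
\(y = (\O/2)\cos\theta\), \(z = (\O/2)\sin\theta\). Finally the
projected trajectory drops z. The unrolling map is an isometry — each
step's geodesic length on the cylinder equals the planar step length
exactly — so the cylindrical walk is genuine surface Brownian motion,
and all three geometries share the *same* underlying walk, which makes
the geometry comparison paired rather than ensemble-vs-ensemble.

Angles are stored unwrapped (no modulo) so the arc-length history
survives; the initial angle is uniform on \([0, 2\pi)\) per trajectory
(a fixed value is available for tests). The walk starts at the origin;
MSD statistics are translation invariant, so the choice is free.

Randomness is reproducible by construction: each trajectory's seed is a
fixed linear hash of (master seed, grid-cell index, trajectory index)
into \([0, 2^{31}-1)\), feeding R's Mersenne–Twister. Ensembles are
therefore bit-identical across runs and independent of iteration order.

## MSD and fitting conventions

The time-averaged MSD over a trajectory of \(N\) steps is
\(\mathrm{MSD}(n\,dt) = (N-n)^{-1}\sum_i |\mathbf r_{i+n}-\mathbf r_i|^2\).
Lags are counted in frame units, so blinking gaps simply remove pairs
(each surviving pair still enters at its true lag). \(D\) is fitted by
unweighted OLS on MSD points 2–5 (lags \(2dt\)–\(5dt\), four points) with
\(4Dt+b\) in 2D and \(2Dt+b\) in 1D; the offset \(b\) absorbs static and
dynamic localization error and may be negative. Trajectories with
\(D < 10^{-4}\,\mu m^2/s\) are classified immobile — below that, apparent
motion is indistinguishable from ~10 nm localization noise. Both the
per-trajectory fit pathway and ensemble-averaged MSD curves are exposed,
since published datasets use either.

For trajectories on the cylinder analysed with all three coordinates,
the MSD is still fitted with \(4Dt+b\): diffusion happens on a
two-dimensional surface whatever the embedding, and this is the only
convention under which the 3D-coordinate estimate converges to the true
\(D\) as \(\O \to \infty\).

Decomposition uses a rotation, not a regression: with axis angle \(a\),
`long = cos(a) x + sin(a) y`, `transv = -sin(a) x + cos(a) y`. Being
orthogonal, it preserves lengths, and `MSD_long + MSD_transv = MSD_2D`
holds at machine precision — one of the package's invariant tests. The
longitudinal 1D fit (`estimate_longitudinal_D()`) is the recommended,
curvature-free estimator: transverse geometry never enters it.

## The bias parameter and master curves

The bias collapses onto the dimensionless parameter

\[\varepsilon = \frac{4 D\, dt}{\O^2},\]

the squared ratio of the RMS in-plane step between consecutive frames,
\(\sqrt{4 D\, dt}\), to the tube diameter. The constant lives in one
function (`epsilon_parameter()`) so an alternative step summary would
change nothing else. Asymptotics follow from the projection geometry:
for \(\varepsilon \to 0\), projecting \(y = (\O/2)\cos\theta\) halves
the transverse MSD contribution (\(\langle\sin^2\theta\rangle = 1/2\)),
giving \(D_{proj}/D_{actual} \to 3/4\), while the 3D-coordinate
estimate is unbiased; for large \(\varepsilon\) the transverse
coordinate decorrelates within one frame and only the longitudinal half
of the motion survives, driving both ratios to \(1/2\).

`build_bias_table()` measures the full curve by simulation on a grid
(by default 8 diffusivities × 6 frame intervals × 8 diameters, 50
trajectories of 1000 steps per cell — the survey regime of typical QD
SPT experiments). A pre-computed table over that default grid ships
with the package, with its generating seed and configuration recorded
in the file's JSON header so it can be regenerated exactly.

`predicted_ratio()` interpolates the master curve: cells are binned
geometrically in \(\varepsilon\) (20 bins per decade — raw cell-to-cell
scatter is substantial at low \(D\)), bin means are made monotone
non-increasing by isotonic regression (the physics guarantees
monotonicity; raw Monte Carlo noise does not), and queries outside the
simulated range clamp to the nearest asymptote with a warning rather
than extrapolate. `correct_diffusivity()` inverts the curve; since
\(\varepsilon\) depends on the unknown true \(D\), it iterates the fixed
point \(D^\* = D_{meas}/r(\varepsilon(D^\*))\) to \(10^{-6}\) relative
tolerance (the map is a contraction here; convergence takes a handful
of iterations) and propagates the across-trajectory SD of the bin ratio
into a band.

## Tube diameter from SPT data

Four estimators, in decreasing order of data appetite:

**Transverse profile fit.** Points uniform on a tube surface project to
the arcsine density \(p(y) = 1/\big(\pi\sqrt{(\O/2)^2-(y-y_c)^2}\big)\)
— highest at the tube edges, since the projected position changes
slowly with angle there. Localization error, tube fluctuations and
shape imperfections smear it; the measurable profile is the convolution
with a Gaussian of SD \(w\). The substitution \(y' = y_c + (\O/2)\sin u\)
removes the edge singularities, leaving a smooth integral evaluated
with a fixed 129-point Gauss–Legendre rule (stable to `1e-6` under
refinement; tested). "Width" means standard deviation throughout: that
convention makes \(\mathrm{Var} = \O^2/8 + w^2\) exact, which is both a
test invariant and the source of moment-matched starting values.
The fit minimizes least squares against a density-normalized histogram
(bin width `max(5 nm, Freedman–Diaconis)`); an unbinned
maximum-likelihood objective is available, and the two agree on
well-sampled clouds. Multi-start over \(w_0 \in \{10, 50, 100\}\) nm
with \(\O_0 = 2\sqrt{2(\hat\sigma^2 - w_0^2)}\) avoids the
\(\O \leftrightarrow w\) trade-off minima. Because the target is a
stochastic distribution, at least ~2000 localizations are required
(the default refusal threshold); a long straight tube segment is
implicit. Parameter uncertainties come from the local curvature of the
objective at the optimum.

**Transversal MSD plateau.** Confinement makes the transverse 1D MSD
saturate at twice the variance of the projected coordinate,
\(\O^2/4\), so \(\O = 2\sqrt{P}\). The plateau is the mean over the
final third of lags, accepted only if the relative slope across that
stretch is below 0.15; a still-rising curve is an error, not a number.
Smearing adds to the plateau, so this estimator reads high on noisy
data — the tests assert exactly that ordering against the profile fit.

**Envelope rectangle.** For clouds too sparse to fit, the tube is
reconstructed as a rectangle: the cloud is cut into stations along the
axis (at least 4 populated ones required) and the transverse width
measured per station, by default as the inner 1–99% span (strict
min–max is available). Mean ± SD over stations.

**Mechanics.** For tethers pulled from vesicles at known tension
\(\sigma\) and force \(f\), \(\O = f/(2\pi\sigma)\) — the independent
physical cross-check, valid for \(\sigma\) around
\(10^{-6}\)–\(4\times10^{-5}\) N/m.

The axis itself is fitted by total least squares (principal axis of the
position covariance): unlike ordinary regression it treats x and y
symmetrically, so the fitted diameter is equivariant under rotating the
field of view — also a test. Nearly isotropic clouds trigger a warning
since their axis is meaningless.

## Astigmatism z-calibration

A cylindrical lens makes spot ellipticity \(w_x/w_y\) a monotone
function of axial position over a limited range (~400 nm, with 50–70 nm
accuracy in the emulated configuration). `build_z_calibration()` keeps
the maximal contiguous strictly monotone stretch of the calibration
series — beyond it, defocus turns the curve over and ellipticity stops
determining z — and builds a monotone piecewise-cubic (Fritsch–Carlson)
interpolant from ratio to z: exact at the nodes, no overshoot between
them. Ratios outside the calibrated range are flagged `NA`, never
extrapolated; `attach_z()` either drops such frames (leaving a
blink-like gap the frame-indexed MSD handles correctly) or masks them.

## The synthetic dataset generator

`generate_tube_dataset()` emulates a QD-on-tube SPT recording: surface
Brownian motion on a cylinder, projected, rotated to an arbitrary
in-plane axis angle, plus Gaussian localization noise and i.i.d.
per-frame blinking dropouts. Defaults are chosen as a realistic
experiment of this kind: \(D = 0.25\,\mu m^2/s\) (lipid-scale mobility
on a tube), \(\O = 300\) nm, \(dt = 15.7\) ms, 1000 frames, 10 nm
lateral and 60 nm axial noise, 10% per-frame dropout (QD blinking is
heavy-tailed in reality; an i.i.d. rate of this order reproduces
realistic mean track lengths without modelling power-law off-times).
Ground truth is returned alongside, and the package's own estimators
recover it in closed-loop tests.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: trajectory-linking errors between
blinks, curved or flexing tubes (straight segments only), tube radius
fluctuations in time, hydrodynamic slowdown in very thin tubes,
membrane-composition heterogeneity, and anomalous or corralled
diffusion modes. On real neurites, adhesion-induced flattening can also
shift the observed ratios away from the ideal-cylinder prediction.

## Problem sizes and numerical choices

Simulation-backed checks in the test suite use 20–50 trajectories of
1000 steps per condition — the scale at which ensemble means of the
bias ratios are stable to a few percent, and the scale the package's
own survey grid uses per cell. The bundled master table is the full
default grid (384 cells × 50 trajectories). Edge conventions worth
knowing: \(w = 0\) returns the unsmeared arcsine profile (delta-kernel
limit); a zero transversal plateau maps to diameter 0; MSD at lag 0 is
identically 0 and is not stored; frames are 0-based with
\(t = \mathrm{frame} \cdot dt\); all files use µm and seconds.

## Limitations

The bias curves are defined by simulation, not closed form — that is a
feature (no small-\(\varepsilon\) expansion is assumed) but means
queries far outside the simulated \(\varepsilon\) range only clamp to
asymptotes. The correction assumes the diameter is known; combining it
with a diameter *estimated from the same data* correlates the errors of
the two steps. The profile fit's reported uncertainties are local
curvature estimates and will understate the error when the histogram
bins are strongly correlated with tube drift.
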