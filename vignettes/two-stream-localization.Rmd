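---
title: "Two visual streams, one grid code: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two visual streams, one grid code: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(twostream)
```

## The problem

Grid cells in the rodent medial entorhinal cortex fire on a hexagonal
lattice of locations. When the walls of a familiar arena are moved closer
together, the firing fields of some grid-cell modules compress along the
shifted dimension while others are unaffected. `twostream` implements a
computational account of this dissociation: the location signal feeding a
grid-cell module can come from either of two visual mechanisms, and the two
react differently to a barrier shift.

* The **moving feature system** watches the optic flow of features on the
  ground plane, estimates the rat's forward speed and yaw rate from it, and
  path-integrates those velocities into a location. Ground-plane flow does
  not care where the walls are, so this estimate tracks the true (newly
  restricted) positions after a barrier shift and the grid pattern is
  unchanged.
* The **static feature system** triangulates location from the bearings of
  landmarks on the four walls, using positions memorized in the original
  arena. After a shift the sensed bearings conflict with the memorized
  geometry; the model absorbs the conflict into per-axis compression
  factors and rescales, so the estimate "fills" the remembered box and the
  grid pattern compresses in real space.

Either estimate can drive two interchangeable grid-cell generators: an
oscillatory-interference model (velocity controlled oscillator, VCO) that
consumes locations, and a twisted-torus attractor network that consumes
velocities. The dissociation is a property of the location estimates, not
of the grid model.

## Conventions

World frame: x east, y north, z up, centimeters; heading `phi` is measured
counter-clockwise from +x. The camera frame follows the computer-vision
habit of z along the direction of travel with y up, making x point left of
travel so the frame stays right-handed. Azimuth `atan2(X, Z)` is positive
to the left; elevation is positive upward, so ground features sit at
negative elevations given the eye height of 2.5 cm. Angles are radians
internally and degrees in configurations and outputs. The spherical-camera
radius (nominally 1 cm) cancels from every angle and never enters the code.

One deliberate sign decision: the printed rendering of the ground-flow
equation we started from is corrupted in places, so all flow signs were
fixed against a central finite-difference oracle on the projected angles
(`test-projection.R`). Concretely, a feature passed on the left drifts
further left and a feature ahead dips downward while approached; the
translational term of `flow_ground()` carries the sign that reproduces
those derivatives exactly.

## The environment

`build_environment()` scatters 9 features uniformly on each of the six
surfaces (ground, ceiling, four 50-cm walls) of the 150 x 150 cm
configuration-A box -- 54 in total. Configuration B moves the north wall to
y = 100 cm; its features ride along rigidly (we assume they keep their
within-wall positions, which the source does not state), and every feature
whose position falls outside the compressed volume is flagged invisible.
Occlusion is exactly this point-in-box test -- no ray casting between
features. Ceiling features exist only to complete the feature budget;
neither estimator reads them. The vertical field of view is 120 degrees;
azimuth never excludes a feature, standing in for short-term memory of
feature angles across head turns.

## Trajectories

`synthesize_trajectory()` draws forward speeds from a Rayleigh distribution
with peak 13.25 cm/s and yaw rates from a normal distribution with SD
337.93 deg/s, independently at 20 Hz for 50,000 samples (41.67 min).
Heading is updated first, then the position steps along the new heading --
that exact discretization is shared with the path integrator so the
noise-free pipeline is exact to machine precision.

Within 15 cm of a wall, with the heading within 90 degrees of the wall's
outward normal, a two-step avoidance maneuver replaces the drawn values:
the speed drops by half its excess over the 5 cm/s minimum, and the rat
turns toward the inward wall normal plus a uniform random 0-90 degree
overshoot (the randomization prevents periodic corner cycling).

Two details of this maneuver were genuinely open and are our choices:

* **Turn duration.** Executing the full turn within one 50-ms sample
  writes yaw rates of thousands of deg/s into the trajectory and inflates
  the fitted yaw SD to ~600 deg/s; spreading it over a second leaves the
  rat trapped in the wall band. We execute the turn at a rate that
  completes it in about a quarter second. With that choice the fitted
  statistics of a synthesized session (Rayleigh peak ~13.1-13.2 cm/s, yaw
  SD ~350 deg/s, slightly below / above the generative values respectively)
  reproduce the published measured reference values of this protocol to
  within a few percent -- the residual bias is the expected footprint of
  the avoidance maneuvers.
* **Containment fallback.** If an extreme draw would still exit the box,
  the position is clamped 0.1 cm inside and the step's recorded speed and
  yaw are rewritten to the realized displacement. Recorded velocities
  therefore *always* integrate exactly to recorded poses (a hard invariant
  of the test-suite); clamps are counted in an attribute and are absent to
  rare (a handful per 50,000 samples) under defaults.

The default start pose is (1, 1) cm -- nudged just inside the reference
corner so the pose is strictly interior -- with heading 0.

Collision checks use the current position, not a look-ahead.

## Moving feature system

For ground features the analytic flow under forward speed `v_z` and yaw
`omega_y` is linear in both, so `estimate_velocity()` minimizes the summed
squared deviation between sensed and modeled angular velocities and solves
the resulting 2 x 2 normal equations in closed form. The test-suite checks
this against a grid-plus-BFGS minimization of the functional itself. On
noise-free flow the recovery is exact; `integrate_path()` then reproduces
the trajectory to machine precision. Only the 9 ground features enter;
features under the rat (elevation below -60 degrees) drop out of the
per-step sums.

Path integration sums the *estimated* yaw into the heading (not the true
heading), which is what lets biased noise corrupt the heading and hence
position without bound. Noise-free, the two are identical.

## Static feature system

Each sample is solved independently. With `psi_i` the allocentric bearing
of wall landmark `i` (egocentric azimuth plus heading) and `(x_i, y_i)` its
memorized configuration-A position, the unknowns are the location
`(x_s, y_s)` and two compression factors `eta` (x) and `xi` (y). Two
families of squared residuals are combined:

* **Triangulation terms** (weight `1 - alpha`): the ray from `(x_s, y_s)`
  toward the compression-adjusted memorized landmark -- `(x_i, xi * y_i)`
  for north/south landmarks, `(eta * x_i, y_i)` for west/east -- must point
  along `psi_i`, with an unknown range `lambda_i`. Each `lambda_i` appears
  quadratically in exactly two residuals, so its stationarity condition is
  linear; substituting it back collapses the pair into the perpendicular
  deviation of the adjusted landmark from the observed ray.
* **Box-dimension terms** (weight `alpha = 1e-4`): for every pair of
  landmarks on opposite walls, stacking their two right triangles forces
  the apparent wall separation to equal `xi * L` (north-south) or
  `eta * W` (west-east), with `L = W = 150` cm the memorized dimensions at
  all times.

Everything is linear in `(x_s, y_s, eta, xi)`, giving a symmetric 4 x 4
system solved in closed form (and, across a whole trajectory, by a
vectorized Cholesky factorization). The final location rescales by the
factors, `x = x_s / eta`, `y = y_s / xi`. The printed source equations for
the per-wall angle conventions and the range constraints are mutually
inconsistent as typeset, so the functional here is re-derived from the
triangle geometry; the test-suite pins it to a brute-force minimization of
the full functional with every `lambda_i` kept free.

Self-consistent observations give the exact position with
`eta = xi = 1`. In the compressed box the solution is again exact:
`xi = 2/3`, and rescaling maps the true range [0, 100] onto the remembered
[0, 150]. Degenerate opposite-wall pairs (near-vertical bearings with huge
tangents) are kept -- the least-squares weighting handles them -- and only
a genuinely singular system raises an error. Elevation angles are observed
(and perturbed by angle-domain noise) but the triangulation consumes only
azimuths; elevations enter the signal-to-noise bookkeeping.

## Grid models

**VCO.** A spike is emitted when the product of three interference pairs
`cos(wt) + cos(wt + w beta x . b_k)` exceeds 1.8, with theta frequency
7.38 Hz and basis vectors at 0/120/240 degrees. The location signal is
consumed directly. `beta = 0.004` (dorsal, moving system) and 0.003
(ventral, static system) imply grid spacings `2/(sqrt(3) beta f)` of about
39 and 52 cm; the band spacing `1/(beta f)` and the map spacing are
verified empirically from simulations rather than asserted, because the
printed closed form is typeset ambiguously.

**Attractor.** 9 x 10 cells on a twisted torus (unit square, y scaled by
sqrt(3)/2; distances are minima over the seven wrap-around copies with the
half-row twist). Per step the weight matrix is a Gaussian (SD 0.24 torus
units) of the twisted-torus distance shifted by the gain-scaled velocity,
minus an inhibition offset 0.05; activities update through the weight
matrix, are mixed with the previous drive normalized by the summed
activity, and half-wave rectified. The readout cell (`n_x n_y - n_y/2`) spikes
above 0.1. Two details worth flagging:

* The printed activity update can be read with the normalization dividing
  only the history term or the whole mixture. The whole-mixture reading is
  unstable -- it sets off a growing two-cycle of the summed activity -- so
  the implementation uses the literal printed reading (history term
  normalized), which converges to the same bump array as the conventional
  formulation in which both terms use the new drive.
* The velocity signal is in cm/s and the gain `alpha` (1.4e-3 dorsal,
  0.9e-3 ventral) is per update step; the bump then crosses one torus
  period per `1/(20 alpha)` cm of travel, giving usable spacings of ~36
  and ~56 cm inside a 150-cm box. Interpreting the input in m/s would put
  the spacing at tens of meters and no grid would fit the arena. The
  Gaussian width is likewise a torus-unit quantity, not meters.
  Where the defaults conflict between the parameter table and a figure
  caption of the source protocol (cell counts, synaptic strength, ventral
  gain), the parameter table wins; the caption variant ships as
  `inst/extdata/config_s1_attractor.yaml`.

For the static feature system the attractor consumes the temporal
difference of the location estimates (`location_velocity()`), which is how
a compressed location estimate turns into a stretched velocity signal and
a compressed firing pattern.

## Noise and its bookkeeping

`noise_spec()` describes i.i.d. Gaussian noise in one of two domains:
angular velocities of ground features (moving system; deg/s) or angular
directions of wall landmarks (static system; deg). Fresh draws per
feature, per component, per step. The two parameterizations of the study
are bias-free (0, 1.75 deg/s) / (0, 1 deg) and biased (1, 1.75 deg/s) /
(0.8, 1 deg).

The domain-independent SNR is `20 log10(sum(s^2) / sum((m - s)^2))` --
twenty, not ten, times the log of a power ratio. That is unconventional
but deliberate: it is the printed definition of the protocol this package
reproduces, and all dB values reported here are produced by it. For the
velocity domain the signal is the azimuth rates of the ground features
(noise is drawn for the elevation rates too); for the angle domain the
azimuths and elevations of wall landmarks are concatenated. Under this
definition the velocity-domain signal power is dominated by the yaw-rate
variance, so its SNR sits near `40 log10(sigma_omega / sigma_v)`; the
reported values are whatever `observation_snr()` computes on the actual
session.

**Brownian error statistics.** Integrating the per-step speed and yaw
estimates directly (radial distance `l = dt * sum(v)`, angle
`phi = dt * sum(omega)`, no Cartesian transform) turns i.i.d. per-step
estimation errors into a random walk: the mean squared error after `n`
steps is `n sigma^2 + n^2 mu^2` with `mu`, `sigma` the per-step error
moments. `brownian_error_stats()` overlays that two-term model on the
across-trial measurement; bias-free noise gives the linear term only,
biased noise adds the parabola. The Cartesian-integrated position does
*not* follow this model -- the polar-to-Cartesian transform mixes the
errors -- which is why the moving system's Euclidean error saturates
under bias-free noise but drifts without bound (toward and past the
sqrt(2) x 150 = 212.13 cm in-box ceiling) under biased noise, while the
static system's error is stationary by construction. The model curve is
checked at long lags; at short lags the measurement sits slightly above it
because the shared trajectory starts near a corner, where flow geometry is
least favorable and the per-step error variance is above its session
average.

## Rate maps, gridness, compression scan

Rate maps bin true positions at 3 cm, smooth occupancy and spike counts
with a 3-cm Gaussian, divide, and mask bins with under 100 ms raw
occupancy. These construction details are not specified by the source
protocol; they follow standard rodent-ephys practice, are exposed in the
configuration, and the scan argmax is insensitive to them within reason.

The gridness score is *this package's* definition (the field-standard
annulus-based rotational score: min of the 60/120-degree autocorrelogram
correlations minus max of 30/90/150), because the source protocol reports
grid scores without defining them; published grid-score values are
therefore never comparison targets.

`compression_scan()` expresses candidate compressions as percentages of
the 50-cm barrier shift: at `p` percent, map B's extent along the scanned
axis is stretched by `p/100 * 50` cm, resampled bilinearly onto map A's
grid over the overlapping extent, and scored by squared Pearson
correlation over jointly valid bins, sampled every 0.5 % over [-20, 120].
We rescale the *map*, not the location series (either is defensible; the
map variant matches how the experimental compression analyses are done
and needs no re-simulation). Scan symmetry and recovery of known imposed
compressions are property-tested.

## Problem sizes

The full study conditions -- 50,000 samples, both configurations, both
systems, 100-trial noise statistics -- run in a few minutes on one CPU and
are exercised by the acceptance suite and `scripts/acceptance.R`. The unit
tests use shorter sessions (1,500-20,000 samples), which we consider ample
for the properties they check: exactness properties are length-independent
and the statistical ones carry explicit tolerances.

## What the generator does and does not emulate

The synthetic world has featureless-but-identified landmarks (perfect
correspondence, no appearance model), a rat with zero pitch and roll whose
gaze is locked to the running direction, instantaneous 360-degree azimuth
knowledge, and additive Gaussian observation noise. Passing tests show the
two-stream mechanism behaves as designed under those idealizations; they
say nothing about feature tracking, occlusion among objects, vestibular
contributions, or real rats' movement statistics beyond the fitted
Rayleigh/normal marginals.

## Known limitations

* The static system assumes the heading used to allocentrize bearings is
  known exactly; heading error would smear the triangulation.
* Compression factors are solved per frame with no temporal smoothing
  (deliberately, to keep frame independence), so angle noise makes
  `eta`, `xi` jitter rather than drift.
* The attractor readout is a single cell; population statistics are out of
  scope.
* A single arena family (axis-aligned rectangles) is supported.
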