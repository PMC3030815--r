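---
title: "Methods: multi-camera 3D multi-target tracking in mvtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-camera 3D multi-target tracking in mvtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvtrack)
```

# The estimation problem

mvtrack reconstructs the 3D position and velocity of several small flying
animals (flies, hummingbirds) from synchronized, calibrated camera views.
Each camera reports, per frame, a short list of 2D blob detections
`z = (u, v, alpha, beta, theta, epsilon)`; nothing identifies which
detection belongs to which animal, detections are sometimes missing
(occlusion, low contrast), and extra detections appear (reflections,
sensor noise). The tracker therefore solves three coupled problems every
frame: *state estimation* (where is each animal), *data association*
(which detection belongs to which animal) and *track management* (when
does a new animal appear, when has one left).

The design follows the architecture of real-time multi-camera insect
trackers: an extended Kalman filter (EKF) per target, nearest-neighbour
standard filter (NNSF) data association with cheap gates, and
birth/death handled by triangulation hypothesis testing and a covariance
threshold. This package runs the identical algorithmic sequence offline,
replacing the camera buses and network transport of a live rig with an
in-process frame iterator, which preserves the order of operations while
making every stage testable against ground truth.

# State model

Each target carries `Gamma = {s_hat, P}` with state
`s = (x, y, z, vx, vy, vz)` in metres and metres per second. The process
model is a constant-velocity particle,

    s_t = A s_{t-1} + w,   A = [I, dt*I; 0, I],   w ~ N(0, Q),

so manoeuvring is absorbed into the process noise `Q`. The defaults are
`Q = diag(1e-4, 1e-4, 1e-4, 0.25, 0.25, 0.25)` — 100 mm² on position and
0.25 m²/s² on velocity — which suit fruit-fly flight sampled near 100
frames per second: saccades are fast relative to the frame interval, so a
tight position noise combined with a loose velocity noise lets the filter
re-acquire the velocity within a few frames of a turn. Positions are
stored in m² (the mm² figure is converted once, at the definition).

The observation is the concatenation of the distortion-corrected image
points of the contributing cameras, `h(s) = (u_1, v_1, ..., u_n, v_n)`,
with `R = r_px * I` and `r_px = 1` px² by default (one-pixel detection
noise). `h` is the projective pinhole map through each camera's 3×4
matrix; its Jacobian is analytic (quotient rule on the dehomogenization)
and zero in the velocity columns. Because `h` is nonlinear the update is
an EKF; triangulation happens only *implicitly* during tracking, which is
what lets a single camera still reduce uncertainty transverse to its
viewing ray while leaving the along-ray variance to grow — tracking
survives short single-camera intervals, at the cost of an elongated
covariance ellipsoid.

Numerical choices: the update is a single stacked update over the
contributing cameras (equivalent to, and simpler than, sequential
per-camera updates); the covariance uses the Joseph form and explicit
symmetrization so `P` stays positive-semidefinite over long runs. With an
empty observation set the posterior is simply the prior — the missing-data
rule — and a counter of unobserved frames is incremented.

# Data association

The NNSF treats targets independently: for each target and each camera it
selects the detection maximizing a likelihood score, or none. The score
is a product of three factors, evaluated cheapest first:

1. **pixel gate** — the detection must lie within `max_pixel_dist`
   (default 20 px, inclusive at the boundary) of the projected prior
   position;
2. **area gate** — the blob area statistic must be *strictly* greater
   than `min_area` (default 1), reflecting that a genuine animal blob has
   measurable extent;
3. **ray term** — `exp(-d²/2)` where `d` is the Mahalanobis distance,
   under the prior's positional covariance, from the prior mean to the
   closest point on the detection's back-projected ray. The closest point
   has a closed form (the minimizer of a convex quadratic along the ray).

If either gate fails, the ray term is never computed — the product is
zero regardless, and the short-circuit is what keeps per-frame cost low
under clutter. The Gaussian kernel is one of several monotone decreasing
functions of `d` that would give identical argmax decisions; it is chosen
for its natural probabilistic reading. Ties in the argmax go to the
lowest feature index, making the assignment deterministic.

**Merge prevention.** When two targets fly close, both may claim exactly
the same detection set. A single pass after assignment finds groups of
targets with identical non-empty assignment sets and keeps only the
target whose predicted observation is closest (summed image distance);
the others are updated without any observation that frame. Exact distance
ties go to the lowest target id. The suite verifies that no two live
targets ever carry identical non-empty assignment sets, and that both
identities survive close crossings in the large majority of seeded
trials.

**Birth.** Detections unclaimed by any existing target enter an unguided
hypothesis test: every combination of 2, 3, ..., n cameras with one
unclaimed detection per chosen camera is triangulated, and among
hypotheses whose mean reprojection error is below
`max_reproj_error_birth` (default 3 px) the one using the most cameras
wins (ties: lowest error). The winner seeds a target at the triangulated
point with zero velocity and a deliberately high initial covariance
(defaults 0.01 m² position, 1 m²/s² velocity per axis) so the first few
updates dominate the estimate. Hypothesis enumeration is capped
(`max_birth_combinations`, default 10,000) to bound the worst-case cost
under clutter bursts; the overflow case defers the excess to the next
frame, where fewer detections are typically unclaimed.

**Death.** A target is retired when the trace of its *positional* 3×3
covariance block exceeds `max_covariance_trace_death`, or after more than
`max_frames_unobserved` frames without any observation. The positional
trace is used because the velocity variance is dominated by `Q` within a
few unobserved frames and would make the criterion insensitive to the
tuning. Retirement is permanent: a re-detected animal becomes a new
identity, and stitching identities across gaps is left to downstream
analysis.

# Feature extraction

Frames are matrices with pixel `(0, 0)` at the centre of the top-left
pixel, `u` rightward, `v` downward. The background is a per-pixel
running-Gaussian model (mean and variance), refreshed only every
`update_interval` frames (default 500) so that slow illumination drift is
tracked while an animal passing through does not contaminate the model.
Detection thresholds the absolute difference image; an optional per-pixel
`k·sigma` mode uses the variance image.

Suprathreshold pixels are grouped by 8-connectivity (a deliberate choice:
diagonal adjacency matters for few-pixel blobs). For each region, a
square window around the peak is analysed: pixels below
`clear_fraction * beta` (default 0.3 of the peak difference) are zeroed
to suppress spurious moment arms, and image moments of the remaining
difference mass give the area statistic `alpha` (0th moment), the
sub-pixel centre (1st moments), the principal-axis slope `theta` in
`[0, pi)` and the eccentricity. Eccentricity is defined as
`sqrt(1 - lambda2/lambda1)` from the eigenvalues of the normalized
second-moment matrix — 0 for isotropic blobs, approaching 1 for line-like
ones; a perfectly symmetric patch (including a single pixel) reports 0.
Orientation of near-isotropic blobs is numerically meaningless, which is
why downstream consumers should gate on eccentricity before using
`theta`.

# The simulator and what passing tests mean

The synthetic module is first-class, tested code. Its defaults are the
small-rig study conditions: five cameras around a 0.3 × 0.3 × 1.5 m
arena at 100 fps, one-pixel detection noise, flight speed regulated near
0.15 m/s. An 11-camera, 2 m diameter × 0.8 m arena is exercised as the
large preset. Cameras are placed on a ring with alternating elevation
(non-coplanar centres), aimed at the arena centre, with focal length
chosen so every arena corner projects inside every image.

Trajectories are straight constant-speed segments (speed drawn within 5%
of the set point) punctuated by saccades — 90–150° turns spread over 2–5
frames about a near-vertical axis, at Poisson times (default 0.5/s) —
with reflective confinement at the walls. Observations add isotropic
Gaussian pixel noise, per-camera Bernoulli misses and Poisson clutter
whose blob statistics are drawn from the same distribution as true
detections (so area gating is a meaningful test, not a free win).
Rendered frames draw Gaussian blobs, optionally elongated along the
projected velocity, on a static textured background.

Everything is a deterministic function of the config seed; each generator
uses its own derived stream so trajectories do not change when rendering
is added.

What the simulator does *not* emulate — and what passing tests therefore
do not demonstrate — includes: correlated (non-Gaussian) detection noise
from specular reflections; occlusion geometry (misses are independent
coin flips, not view-dependent); interaction between animals (pursuit,
contact); wing-beat appearance changes; rolling-shutter or
desynchronized cameras; and calibration error in the rig itself (the
tracker receives the true matrices except in the calibration tests,
which perturb them through noisy DLT).

# Problem sizes and numerical tolerances

The test and acceptance workloads are sized for a desk machine: 1000
frames for the reprojection-precision check, 200 replicates for the
noisy-DLT distance-accuracy check, 1000 random instances for the
NNSF-vs-brute-force equivalence, 100 seeded crossings for merge
prevention, 150-frame tracking runs for the RMSE figure. Undistortion
iterates to 1e-8 px (max 20 iterations); triangulation and DLT use SVD
with Hartley normalization and no iterative refinement; degenerate
configurations (single camera, parallel rays, coplanar calibration
points) are errors, not warnings.

Derivative-based trajectory statistics (horizontal speed, angular
velocity) use central differences with one-sided endpoints and no
smoothing by default. On *tracked* trajectories, differentiation
amplifies millimetre-scale estimation noise into tenths of m/s; the
`smooth_window` argument (odd, in frames) applies a centred moving
average to positions first, and a window spanning roughly 90 ms restores
the underlying speed at 100 fps. On ground-truth or slowly-sampled data
the default (no smoothing) is exact. The approach angle is signed:
positive means the landmark is to the left of the heading; zero means
flying straight at it.

# Known limitations

- NNSF is a single-hypothesis scheme: under heavy clutter inside the
  gate, or for targets closer than the gate radius for many consecutive
  frames, identity swaps are possible even though merged assignments are
  prevented. Multi-hypothesis or probabilistic association is out of
  scope.
- The constant-velocity model with fixed `Q` is tuned for fly-scale
  flight near 100 fps; slower frame rates or faster animals need `Q`,
  the gate radius and the death threshold re-tuned together.
- Distortion parameters are accepted and applied (two-term radial model
  about an explicit centre) but never *estimated*; calibration here is
  linear DLT only.
- Track identities are not stitched across retirement gaps.
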