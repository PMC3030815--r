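# mvtrack

Multi-camera three-dimensional tracking of multiple flying animals in R.

Behavioural experiments on free flight — visual guidance in flies,
manoeuvring in hummingbirds — need long, accurate 3D trajectories of
unmarked animals. A practical rig films a flight arena with several
calibrated cameras; each camera sees only a few-pixel blob per animal,
detections go missing, and spurious ones appear. `mvtrack` turns those
per-camera blob detections into per-animal 3D trajectories, implementing
offline the full algorithmic core of a real-time multi-target tracking
system:

- **Feature extraction** — running-Gaussian background subtraction and
  image moments give sub-pixel blob centres plus area, peak difference,
  orientation and eccentricity per detection.
- **State estimation** — one extended Kalman filter per target with a
  constant-velocity process model (`s = (x, y, z, vx, vy, vz)`,
  `Q = diag(100 mm², …, 0.25 m² s⁻²)`) and a projective multi-camera
  observation model `h(s) = (u₁, v₁, …, u_n, v_n)`, `R = I` px².
- **Data association** — a nearest-neighbour standard filter per target:
  an image-distance gate, a blob-area gate, and a Gaussian likelihood in
  the Mahalanobis distance from the prior to the detection's
  back-projected ray; a merge-prevention pass keeps targets from sharing
  identical observation sets.
- **Track management** — birth by triangulation hypothesis testing over
  all camera combinations of unclaimed detections; death when the
  positional covariance trace crosses a threshold.
- **Geometry** — pinhole cameras with optional two-term radial
  distortion, DLT calibration, SVD triangulation, plain-text camera
  files.
- **Simulator** — seeded camera rigs, saccade-punctuated flight
  trajectories, noisy/cluttered observations and rendered blob frames,
  with ground truth for every stage.
- **Analysis** — horizontal flight speed, angular velocity of the flight
  tangent, approach angle to a landmark, per-condition unit-area speed
  histograms with a wall-distance filter.

## Worked example

Simulate two flies in a 0.3 × 0.3 × 1.5 m arena viewed by five cameras
at 100 fps with one-pixel detection noise, then track them:

```r
library(mvtrack)

cfg <- sim_config(n_targets = 2, n_frames = 200, pixel_noise_sigma = 1,
                  seed = 42)
ds  <- simulate_dataset(cfg)
res <- track_features(ds$observations$features, ds$rig,
                      tracker_config(dt = 1 / cfg$frame_rate))
str(res$log)
#> List of 4
#>  $ n_frames  : int 200
#>  $ n_features: int 2000
#>  $ n_births  : int 2
#>  $ n_deaths  : int 0
head(res$trajectories, 3)
#>   target_id frame          x       y       z        vx        vy        vz    ptrace ncams
#> 1         1     1 -6.024e-05 0.07491 -0.3971  0.000000  0.000000  0.000000 3.000e-02     5
#> 2         1     2 -7.671e-04 0.07205 -0.4021 -0.000693 -0.002805 -0.004846 1.731e-05     5
#> 3         1     3  3.130e-03 0.07225 -0.3984  0.208150  0.010215  0.196984 1.683e-05     5
```

Both animals are found in the first frame (`n_births = 2`) and tracked
to the end without identity loss. Each row is one posterior state:
position (m), velocity (m/s), the trace of the positional covariance
block (`ptrace`, m² — it collapses from the deliberately high birth value
0.03 to ~2e-5 after one full five-camera update) and the number of
cameras that contributed (`ncams`). Against the simulator's ground truth
the tracked positions have an RMSE of 4.1 and 4.2 mm for the two
targets, and the recovered mean horizontal speed,

```r
sp <- horizontal_speed(res$trajectories[res$trajectories$target_id == 1, ],
                       dt = 0.01, smooth_window = 9)
mean(sp)
#> [1] 0.1480817
```

matches the simulator's 0.15 m/s flight-speed set point (the horizontal
component of a slightly climbing/descending 3D path is a little below
the 3D speed).

A thin command-line front end over the same functions is installed at
`inst/cli/mvtrack` (`simulate`, `extract`, `track`, `analyze`
subcommands).

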