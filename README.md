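# hingecal

Plug-and-play calibration of a hinge joint's axis from two body-worn
inertial measurement units (IMUs).

## The problem

Inertial motion capture of a one-degree-of-freedom joint — a knee, a finger
joint, a robotic hinge — needs the direction of the joint axis expressed in
each sensor's own coordinate frame: a pair of unit vectors \(j_1, j_2\),
one per IMU.  Classical sensor-to-segment calibration demands precise
mounting or prescribed calibration movements inside a fixed initial time
window, and fails silently when the user does not comply.  `hingecal`
implements a calibration that needs neither: it consumes arbitrary motion,
extracts the informative samples wherever they occur in the stream, and
reports an axis estimate only once its own uncertainty accounting says the
estimate is reliable.  The package is aimed at researchers in wearable
inertial motion analysis and at anyone building IMU pipelines around hinge
joints.

## The method

The axes minimize a weighted nonlinear least-squares cost built from two
kinematic constraints of a rigid hinge, summed over samples \(k\):

* gyroscope: \(\lVert y_{\omega,1}\times j_1\rVert -
  \lVert y_{\omega,2}\times j_2\rVert = 0\) (exact for any hinge motion),
* accelerometer: \(j_1^\top y_{a,1} - j_2^\top y_{a,2} \approx 0\)
  (exact when a sensor is near-stationary),

with weights \(w_\omega = \sqrt{w_0}\), \(w_a = 1/\sqrt{w_0}\)
(default \(w_0 = 50\)), over the spherical parametrization
\(x = (\theta_1,\phi_1,\theta_2,\phi_2)\).  The solver is Gauss–Newton
with an analytic Jacobian, damped normal equations and Armijo backtracking,
re-run from the flipped sign pairing \((\theta_1,\phi_1,-\theta_2,
\phi_2+\pi)\) to resolve the rotation-sense ambiguity.  Around it:

* **sample selection** — a windowed angular-rate-magnitude score keeps the
  most one-sided gyroscope samples of both signs; an angular-rate-energy
  threshold plus an SVD-coherence prune keeps accelerometer samples that
  are both trustworthy and mutually novel; both run incrementally on a
  stream with cached scores (at most `n_max` samples per channel);
* **uncertainty quantification** — a covariance-based local metric
  \(\mu_z + 2\sigma_z\) (Monte-Carlo propagated to angular deviations) and
  a global sequential-consistency metric (SEQAD) over independently
  re-initialized estimates; an estimate is accepted when both stay below
  `e_max` (default 3°) for `n_min` (default 10) consecutive batches.

A rigid-body simulator generates all test data: 14 motion presets
(stationary, stiff-joint, sequential, simultaneous planar, free rotation;
slow/fast; horizontal/tilted/free axis) and 4 scenario orderings, with
Gaussian noise and constant biases.  See the methods vignette
(`vignettes/hinge-axis-calibration.Rmd`) for the full model and the design
choices.

## Worked example

Simulate the natural-order evaluation scenario at 8 s per motion and run
the streaming calibration:

```r
library(hingecal)

cfg <- sim_config(seed = 1)
rec <- simulate_scenario("scenario1", cfg, duration = 8)
cal <- run_acceptance(rec,
                      sel_cfg = selection_config(n_max = 1000),
                      unc_cfg = uncertainty_config(n_min = 10),
                      seed = 1)
cal
#> Calibration accepted at t = 27 s
#>   j1 = (-0.0033, 1.0000, 0.0032)
#>   j2 = (0.0017, 1.0000, 0.0049)
#>   27 batches processed
```

The stream contains stationary and stiff-joint motion for the first 16 s;
the axis becomes identifiable once sequential rotation starts, and after
ten consecutive seconds of mutually consistent, low-uncertainty estimates
the calibration is accepted at t = 27 s.  Both axes are recovered to about
0.3° of the simulator's ground truth (\(j_1 = j_2 = (0,1,0)\)).  The
per-batch history is a tibble:

```r
tail(tidy(cal), 3)
#>       t  cost local1 local2  seqad n_gyro n_accel ...
#>      25  6.64  0.194  0.195 0.0528   1000    1000
#>      26  6.63  0.181  0.196 0.0324   1000    1000
#>      27  6.32  0.154  0.184 0.0665   1000    1000
```

`local1`/`local2` are the per-axis local uncertainty metrics and `seqad`
the sequential angular deviation, all in degrees; `autoplot(cal)` draws
them against the acceptance threshold.  A shell entry point wrapping the
same functions lives at `inst/cli/hingecal.R`
(`simulate | calibrate | experiment` subcommands).

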