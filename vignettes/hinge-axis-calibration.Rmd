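---
title: "Plug-and-play hinge-joint axis calibration: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plug-and-play hinge-joint axis calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingecal)
```

## The problem

Two inertial measurement units (IMUs) are strapped to the two segments of a
one-degree-of-freedom joint — a knee, a finger joint, a robotic hinge.  Each
IMU reports angular velocity $y_\omega$ and specific force $y_a$ in its own
sensor frame, which is related to the segment's anatomy in an unknown way.
Before any joint angle can be computed, the direction of the hinge axis must
be identified *in each sensor frame*: a pair of unit vectors $(j_1, j_2)$.
`hingecal` estimates this pair from arbitrary motion, decides on its own
when the estimate is reliable, and refuses to report an axis when the
observed motion cannot identify one (for example when the joint never flexes
— "stiff-joint" motion).

## Measurement model and kinematic constraints

The gyroscope and accelerometer models are

$$y_\omega = \omega^S + b_\omega + e_\omega, \qquad
  y_a = R^{SG}\,(a^G + g^G) + b_a + e_a,$$

with constant biases $b$ and i.i.d. Gaussian noise $e$.  Rigid-body
kinematics of a hinge gives two constraints that hold at the true axes for
every sample $k$:

* **Angular velocity** — the components of the two angular velocities
  perpendicular to the axis have equal magnitude:
  $\lVert y_{\omega,1} \times j_1 \rVert - \lVert y_{\omega,2} \times j_2
  \rVert = 0$.  This holds exactly for a rigid hinge, for any motion.
* **Acceleration (approximate)** — the joint-centre acceleration projects
  equally on the axis seen from both sides, so
  $j_1^\top y_{a,1} - j_2^\top y_{a,2} \approx 0$; the neglected part is the
  rotational acceleration of each sensor's offset $r_i$ from the joint
  centre projected on the axis, which is small whenever at least one sensor
  is close to stationary.

Both constraints become weighted residuals
$e_\omega = w_\omega(\lVert y_{\omega,1}\times j_1\rVert -
\lVert y_{\omega,2}\times j_2\rVert)$ and
$e_a = w_a (j_1^\top y_{a,1} - j_2^\top y_{a,2})$, and the axes minimize
$V(x)=\sum_k e_\omega^2 + e_a^2$ over the spherical parametrization
$x=(\theta_1,\phi_1,\theta_2,\phi_2)$,
$j_i = (\cos\theta_i\cos\phi_i,\ \cos\theta_i\sin\phi_i,\ \sin\theta_i)$,
which enforces unit norm by construction.

A single ratio $w_0 = w_\omega/w_a$ (implemented as $w_\omega=\sqrt{w_0}$,
$w_a = 1/\sqrt{w_0}$) sets the relative weighting.  The default $w_0 = 50$
reflects that angular rates in rad/s are numerically smaller than
accelerations dominated by gravity ($\approx 9.82$ m/s$^2$), and that the
gyroscope constraint is exact while the accelerometer constraint is
approximate.  The weight-sweep experiment
(`experiment_weight_sweep()`) shows a broad insensitive band, roughly
$w_0 \in [10, 10^5]$, on informative motions.

### Sign pairing

$(+j_1,+j_2)$ and $(-j_1,-j_2)$ describe the same physical axis;
$(\pm j_1, \mp j_2)$ reverses one sensor's rotation sense and is wrong.
The gyroscope residual is *blind* to the pairing (it only sees norms), so
the pairing is decided by the accelerometer term.  `estimate_joint_axis()`
therefore re-runs the solver from the flipped pairing
$(\theta_1,\phi_1,-\theta_2,\phi_2+\pi)$ and keeps the candidate with the
smaller cost.  When the two candidate costs agree within
$10^{-12}\max(1,V)$ the data cannot decide the pairing; the fit is flagged
`pairing_ambiguous` instead of pretending to know.  As $w_0 \to \infty$ the
accelerometer term drowns numerically and the pairing decision degrades to
a coin flip — reproduced by the package's tests as RMSAE $\to 90^\circ$
over the deterministic start grid.

Note one subtlety the simulator exposes: with an axis *exactly* orthogonal
to gravity, a fixed carrier and no joint-centre acceleration, gravity has no
component along the axis and the pairing is unidentifiable *in principle*,
not just numerically.  Physical rigs are never aligned exactly, so the
simulator's "horizontal" presets use a 5° elevation offset — the axis is
approximately orthogonal to gravity, as a hand-aligned physical rig would
have it.

## Solver

`gauss_newton()` iterates
$x \leftarrow x - \alpha\,(J^\top J + \lambda I)^{-1} J^\top e$ with the
analytic Jacobian (the only non-trivial entries are
$\partial\lVert y\times j\rVert/\partial j = ((y\times j)\times
y)/\lVert y\times j\rVert$, chained through
$\partial j/\partial(\theta,\phi)$).  Numerical choices:

* **Damping** $\lambda = 10^{-12}\,\mathrm{tr}(J^\top J)/4$: on
  non-informative data $J^\top J$ is singular along the unidentifiable
  directions; plain inversion would fail where graceful degradation is
  wanted.
* **Line search**: Armijo backtracking from $\alpha=1$ (shrink 0.5,
  sufficient-decrease constant $10^{-4}$, floor $10^{-8}$), so the cost
  sequence is provably non-increasing.
* **Termination**: $|\Delta V| < V_{\mathrm{tol}} = 10^{-10}$, line-search
  failure, or 200 iterations.  The iteration cap is a safety net for
  large-residual basins where Gauss–Newton converges slowly; the candidate
  produced there always loses the cost comparison, so the cap does not
  affect the reported axes.
* **Degenerate samples**: where $\lVert y_{\omega,i}\times j_i\rVert = 0$
  (a stationary sensor) the norm is not differentiable; the corresponding
  Jacobian contribution is set to 0, a valid subgradient that avoids NaNs.
* The accelerometer residual uses sensor 2's accelerometer in its second
  term — the only reading that makes the approximate acceleration
  constraint the residual's zero set.

## Sample selection

Long recordings are mostly redundant.  Each channel keeps at most
$N_{\max}$ samples (default 1000):

* **Gyroscope** (`select_gyro()`): the score of sample $k$ is the signed
  rate-magnitude difference
  $\Delta\omega = \lVert y_{\omega,1}\rVert - \lVert y_{\omega,2}\rVert$ of
  smallest magnitude within a $2n{+}1$-sample window (default $n = 21$;
  the windowed minimum discards outliers from non-rigid artefacts).  The
  $N_{\max}/2$ most positive and most negative scores are kept, so both
  sensors' excitation is represented.  The window is truncated at the
  recording edges; scores there are still defined.
* **Accelerometer** (`select_accel()`): samples whose windowed angular-rate
  energy $\min_i E_i$ exceeds $E_{\mathrm{th}} = 1$ rad$^2$/s$^2$ likely
  violate the approximate constraint and are dropped outright (edge samples
  without a full window count as infinite energy).  The remainder is pruned
  one sample at a time: compute the SVD of the retained constraint matrix
  $A$ (rows $(y_{a,1}^\top, -y_{a,2}^\top)$), and remove the worst-penalty
  sample among those whose row is coherent ($c_k > 0.5$) with the first
  right-singular vector — redundant information — until $N_{\max}$ remain.
  If no retained row is coherent the prune removes the worst-penalty sample
  overall; without this fallback the loop could not terminate.  Ties are
  broken by earliest sample index.
* **Online reuse** (`update_selection()`): scores and energies are cached
  per sample and recomputed only where a window straddles new data; the
  accelerometer prune runs over the previously retained set plus newly
  admissible samples.  For the gyroscope this is exactly equivalent to
  batch selection — a score strictly inside both ends of the sorted list
  can never re-enter them.

## Uncertainty quantification and acceptance

* **Local** (`local_covariance()`, `monte_carlo_ad()`): the parameter
  covariance is approximated by $(J_s^\top J_s)^{-1}$ with rows scaled by
  the per-channel residual standard deviation (floored at $10^{-12}$);
  $L = 1000$ Monte-Carlo draws are pushed through the axis map, giving the
  mean and standard deviation of the angular deviation from the estimate.
  The metric is $\mu_z + 2\sigma_z$ per axis; a singular information matrix
  yields an infinite metric, which simply fails the criterion.
* **Global** (`seqad()`): per batch, a fresh area-uniform random start
  (uniform on the sphere per axis, avoiding polar bias) re-solves the
  problem; consecutive sign-aligned estimates are compared by their largest
  per-axis angular deviation, padded with $180^\circ$ before the first
  estimate.  The alignment (`sign_consistent()`) applies one global sign
  only, so a pairing flip between consecutive estimates is detected, not
  hidden.
* **Acceptance** (`run_acceptance()`): accept as soon as both axes'
  local metrics and the last $n_{\min}$ sequential deviations are all below
  $E_{\max}$ (default $3^\circ$, both axes must pass — the stricter,
  monotone-safe reading of the scalar test).  $n_{\min} = 10$ is the
  reliable operating point: with $n_{\min}$ as small as 1–3 the loop can
  accept a spurious but self-consistent minimum before any informative
  motion has been seen.  With two equally deep minima the chance of
  $n_{\min}$ consecutive wrong estimates is $0.5^{n_{\min}}$, which the
  test suite verifies empirically at $n_{\min}=1$.

## The simulator

`simulate_motion()` builds sensor orientations
$R_i(t) = B(t)\,\mathrm{Rot}(u,\alpha_i(t))\,Q_i$: a shared carrier
rotation $B(t)$, segment angles $\alpha_i(t)$ about the axis $u$, and fixed
mountings $Q_i$ with $Q_i j_i = u$.  All angular velocities and
accelerations are closed-form, so the hinge constraints hold to machine
precision — verified against finite differences of $R_i(t)$ in the tests.
Measurements follow the models above, with seeds making noise reproducible.

The 14 presets combine five classes (stationary; stiff-joint rotation;
sequential rotation; simultaneous planar rotation; free rotation) with slow
(0.25 Hz) and fast (×3) variants and horizontal / tilted-45° / free axis
orientations.  Angle profiles are smooth gated sinusoids with ≈45°
amplitude; each motion starts and ends at rest, so concatenating presets
needs no transition removal.  Simultaneous planar presets give the two
segments distinctly different vigour, swapping the leading role halfway —
as hand-performed motion does, and what makes $\Delta\omega$ a usable
informativeness signal; perfectly symmetric sinusoids would be a
pathological corner where the score is honestly uninformative.  Defaults:
50 Hz sampling, $j_1=j_2=(0,1,0)$, offsets $r_1=(0,0,0.1)$,
$r_2=(0,0,-0.1)$ m (so the acceleration constraint is genuinely approximate
during fast motion), gravity 9.82 m/s², noise 0.01 rad/s and 0.1 m/s² —
representative MEMS figures.  Scenario orderings 1–4 reproduce the
evaluation designs: natural order; early one-segment motion; informative
motion early; informative motion only late.

What the simulator does **not** emulate: soft-tissue artefacts, sensor-axis
misalignment and scale errors, bias drift, non-rigid mounting, and the
irregularity of real human motion.  Two consequences matter for
interpreting green tests.  First, smooth periodic motion makes spurious
stiff-joint minima *more* stable than in reality, so the premature
acceptance hazard at small $n_{\min}$ appears here even more readily —
which is the conservative direction.  Second, passing recovery tests on
simulated data show correctness of the estimator and its uncertainty
accounting under the stated model, not field accuracy on human limbs.

## Problem sizes

The test-suite and the acceptance script run scenarios at 8–30 s per
motion, 20 acceptance repetitions, 20-point weight sweeps over
$[10, 10^5]$, and sample budgets $N_{\max} \in \{500, 1000\}$ — sizes
chosen so the whole suite runs in minutes on one core while every
qualitative regime (informative / non-informative, small / extreme $w_0$,
selection on / off, biased / unbiased) is exercised.  The scenario-level
bookkeeping quantities (35 000 samples at 700 s) are computed at full
scale, which costs seconds.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
rec <- simulate_scenario("scenario1", cfg, duration = 8)
cal <- run_acceptance(rec,
                      sel_cfg = selection_config(n_max = 1000),
                      unc_cfg = uncertainty_config(n_min = 10),
                      seed = 1)
cal          # acceptance time and axes
tidy(cal)    # per-batch uncertainty history
autoplot(cal)
```

## Known limitations

* The local covariance is a large-sample Gaussian approximation; on barely
  informative data it can understate uncertainty around spurious minima —
  the global criterion exists precisely to catch this, and $n_{\min}$
  should not be lowered below ~10 in practice.
* Joint-centre offsets $r_i$ are not estimated; large offsets plus fast
  motion bias the accelerometer constraint (mitigated by the energy
  threshold).
* Constant biases are tolerated at realistic magnitudes (the
  bias-robustness experiment); drifting biases are out of scope and should
  be pre-calibrated.
* 2-DOF joints and joint-centre identification are out of scope.
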