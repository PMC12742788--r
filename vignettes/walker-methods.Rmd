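---
title: "Methods: limit-cycle gaits and once-per-step control of the simplest walker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: limit-cycle gaits and once-per-step control of the simplest walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gaitscape` simulates the powered *simplest walker*: a planar biped with
point feet, rigid massless legs, and all mass concentrated at the hip. The
state is the stance angle $\theta$ (from vertical), the swing angle $\phi$
(from the stance leg), and their rates. Because the foot masses are
vanishingly small relative to the hip mass, the swing leg cannot react back
on the stance leg; the stance leg is an inverted pendulum,
$\ddot\theta = \sin\theta$, while the swing leg obeys

$$\ddot\phi = \ddot\theta + \dot\theta^2\sin\phi - \cos\theta\,\sin\phi - k\,\phi ,$$

with hip-spring stiffness $k = k_1$ while $\phi > 0$ (early swing) and
$k = k_2$ while $\phi \le 0$ (late swing). All quantities are dimensionless:
lengths are scaled by leg length $l$, masses by total mass $M$, time by
$\sqrt{l/g}$, so speeds scale by $\sqrt{gl}$ and step frequencies by
$\sqrt{g/l}$.

A step ends when the swing foot reaches the ground, $\phi = 2\theta$. Just
before that contact, a push-off impulse $P$ acts along the stance leg; the
contact itself is a perfectly inelastic collision that swaps the legs:

$$\theta^+ = -\theta^-,\quad
  \dot\theta^+ = \cos 2\theta\,\dot\theta^- + \sin 2\theta\,P,\quad
  \phi^+ = -2\theta^-,\quad
  \dot\phi^+ = (1-\cos 2\theta)\,\dot\theta^+ .$$

The three actuations $(P, k_1, k_2)$ are held fixed within a step and may
change only between steps — once-per-step control.

### Event handling and numerical choices

The contact function $\phi - 2\theta$ is zero at the step start (the
trailing foot is still on the ground) and also vanishes when the point foot
*scuffs* past the ground near mid-stance. A step therefore accepts a contact
only when (i) the swing leg is past the stance leg, $\phi < -10^{-6}$, and
(ii) the foot is descending ($\dot h < 0$ for the foot height
$h = \cos\theta - \cos(\theta-\phi)$). Ascending zero crossings are the exit
of a scuff episode and are ignored, the standard idealization for point
feet. The stiffness switch at $\phi = 0$ is an integration event: the solver
is restarted there so that the discontinuous right-hand side never degrades
the error control. After any event the integrator is nudged past the root by
a single fourth-order Runge-Kutta step of $10^{-8}$ time units (local error
$\sim 10^{-40}$), which prevents immediate re-detection of the same root.

Falls are detected as $|\theta| \ge \pi/2$, or a sign change of
$\dot\theta$ while $\theta > 0$ (the walker rocks back before mid-stance). A
step exceeding 50 dimensionless time units without contact is reported as
`no_contact`. The default integration tolerance is $10^{-13}$ (both
relative and absolute), the root-finding swing dynamics are compiled C
evaluated through `deSolve::lsodar`.

## Periodic gaits and the gait space

The walker's independent state at a step start is $x = (\theta,
\dot\theta)$; the swing states follow from the transition map. The
step-to-step (return) map $F$ takes $x$ at one step start to the next. A
gait is a fixed point $x^* = F(x^*)$ with prescribed step length
$SL = 2\sin\theta_0$ and step frequency $SF = 1/T$. `solve_limit_cycle`
solves the square system (periodicity ×2, the two targets, and — in
double-spring mode — the symmetry equation $k_1 = k_2$) for
$(\theta, \dot\theta, P, k_{1,2})$ with a damped Newton iteration; the
residual tolerance is $10^{-11}$ and push-off is constrained non-negative by
clamping. At a periodic gait the two stiffnesses are equal; they differ
only when feedback perturbs the gait, which is why the grid can be solved
in the cheaper single-spring mode and controlled in double-spring mode.

Warm starts reuse the neighboring solution and its Jacobian; Broyden
rank-one updates keep the Jacobian current so that most continuation solves
need no fresh finite-difference Jacobian at all. A fresh Jacobian is
computed only when a damped step stalls.

### The gait family and its solution branches

The constraint system has several roots at the same $(SL, SF)$ targets,
because the collision resets the swing states from the stance states alone:
distinct stiffness values can deliver the swing foot to the same contact
point at the same time with different approach velocities. Three facts
organize the structure:

* **High-stiffness multi-swing branches** (the swing leg oscillates several
  times before contact, $k$ of order 50 and above) are fragile, expensive
  to integrate and not part of the mapped family; they are rejected by a
  stiffness sanity bound ($|k| \le 30$; the family's stiffness never
  exceeds $\approx 13$).
* Even the long/fast **seed corner** $(1.1, 1.1)$ admits two moderate-
  stiffness periodic solutions ($k \approx 9.70$ with $\max|\lambda|
  \approx 2.7$, and $k \approx 12.43$ with $\max|\lambda| \approx 0.48$).
  The mapped family continues from the lower-stiffness root
  (`family_seed()`): it is the assembly whose stability map has the single
  connected stable central region flanked by the low-frequency and
  high-frequency unstable regions, with the controllability zero-boundary
  coinciding with the high-frequency stability boundary.
* The smooth solution curves **cross and exchange stability** along curves
  in gait space (both roots coincide where an eigenvalue passes $+1$), so
  continuation is *path dependent* near the crossings. The family is
  therefore defined by canonical-path continuation
  (`solve_family_gait()`): from the corner seed along the fast-frequency
  edge in step length, then down each step-frequency column, in 0.01
  steps with secant-extrapolated warm starts. A converged solution that
  lands far from its secant prediction (beyond what curvature allows) is
  treated as a hop onto the crossing branch and re-approached through
  sub-steps; the sub-sampled stability map additionally repairs cells
  whose stiffness is incoherent with their step-length neighbors (the
  family's stiffness varies only weakly with step length) by bridging
  from those neighbors. `audit_smoothness` flags any residual branch jump
  as a parameter discontinuity across adjacent cells.

Initial guesses for cold solves come from an inverted-pendulum estimate
($\theta_0 = \arcsin(SL/2)$, stance rate from pendulum energy plus the mean
angular speed, $k \approx (\pi SF)^2-1$ from matching the swing half-period
to the step time) refined over a small deterministic lattice of candidates.
A deterministic lattice is used instead of random multi-start so that
repeated runs are bit-stable without seed bookkeeping.

Unsolved cells are flagged, never interpolated or fabricated. The extreme
low-frequency edge of the space (SF near 0.1, where the return map's
eigenvalues reach $10^3$–$10^4$ and Newton basins shrink accordingly) is
where unsolved cells concentrate.

## Linearization, stability and controllability

`linearize_gait` builds the discrete model
$\Delta x_{i+1} = A\Delta x_i + B\Delta u_i$,
$\Delta y_{i+1} = C\Delta x_i + D\Delta u_i$ (outputs $y = (SL, SF)$ of the
ensuing step) by one-sided finite differences with perturbation $10^{-7}$ —
large enough to sit far above the $10^{-13}$ integration noise, small
enough for the quadratic remainder to be negligible (the package tests
verify Richardson-style consistency across $10^{-8}$–$10^{-5}$ and
agreement with central differences). Stability is read from the
eigenvalues of $A$; the gait space has a stable central region (mean
largest magnitude ≈ 0.8) flanked by an unstable strip at very low step
frequencies (magnitudes in the thousands) and a mildly unstable band
(magnitudes ≈ 1.2–2.4) along the high-frequency stability boundary that
runs from long-step/medium-frequency gaits to medium-step/high-frequency
gaits.

Controllability uses the rank of $[B, AB]$ with a singular-value ratio
threshold of $10^{-8}$. For the single-spring walker the sensitivities
$A_{12}$, $B_{12}$ and $B_{22}$ (effect of the stance rate and of the
stiffness on the next stance angle and rate) vanish simultaneously along a
zero-boundary locus, where the controllability matrix drops to rank one:
push-off never affects the next stance angle ($B_{11} = 0$ structurally,
since the contact angle is fixed before the impulse acts), so on that locus
no actuation can steer the stance angle. `locate_zero_boundary` refines the
locus by bisection on the $B_{12}$ sign change. Splitting the hip spring
into two independently tunable stiffnesses (early/late swing) moves the
zero crossings of the two stiffness columns to different gaits, restoring
full rank everywhere sampled.

## Deadbeat control

With the control law $u = u_n - K(x - x_n)$ the closed loop is $A - BK$.
`deadbeat_gains` uses $K = B^+ A$ (Moore–Penrose); since the double-spring
$B$ has full row rank, $A - BK = 0$ exactly — all poles at zero, so small
perturbations are eliminated in a single step. With three inputs and two
states the deadbeat gain is non-unique; the pseudoinverse selection is the
minimum-norm solution and is deterministic. Other deadbeat selections (for
example those produced by eigenstructure-assignment pole placers) have the
same zero linear spectrum but can differ in their *nonlinear* response to
large perturbations; this is the main source of spread when comparing
response times at the most gain-sensitive gaits (long steps at low
frequencies).

**Maximum tolerable perturbation (MTP).** For a target gait, the walker is
started from the limit-cycle states of neighboring gaits on concentric
0.01-spaced layers, under either the target's nominal actuation (open
loop) or its deadbeat controller. A neighbor converges if the walker
completes 100 steps without falling and returns to within $10^{-6}$ of
$x^*$ (the run exits early once the error falls below $10^{-8}$, since the
controller holds it there). The MTP is the largest radius — reported at
the 0.01 lattice resolution — whose circle contains only converging
neighbors.

**Response time.** Settling is the number of steps until the realized step
length (or frequency) stays within 5% of the initial deviation from the
target; the discrete series is refined by linear interpolation between the
bracketing steps. The walker arrives on the perturbed limit cycle, so the
arrival step is counted as step one of the error series — its error equals
the initial difference, and the once-per-step controller's adjustment first
shows in the realized gait one heel strike later.

## The interpolated feedback policy

`gain_grid` stores, per grid gait, the six deadbeat gains, the two nominal
stance states and the three nominal actuations; `interpolate_policy`
evaluates all eleven quantities at arbitrary targets by bilinear
interpolation over the enclosing cell (exact at nodes). `track_path`
applies, at each step, the policy interpolated at the next target with the
current state.

**Response-time experiment (15% perturbations).** The walker starts on the
limit cycle of a gait 15% above or below the target in one axis and tracks
an exponential reference $r(s) = \text{target} + (\text{start} -
\text{target})e^{-s/\tau}$ toward the target, the other axis held at the
target value. The shared time constant is optimized by bounded scalar
minimization (Brent) of the summed RMS deviation of the two tracked
trajectories from the target over the reference length; a run that falls
is penalized with a large cost. This cost was chosen deliberately: the RMS
error *between tracked and reference paths* alone is degenerate (a slower
reference is always easier to track, so the time constant diverges),
whereas the deviation-from-target cost balances overshoot from aggressive
references against sluggishness, giving an interior optimum — the fastest
reference the policy can actually follow. The reported response time is
the 5% settling time of the optimal reference, $\tau\ln 20$; the settling
times of the tracked series are reported alongside.

**Sine paths.** Step length oscillates at twice the frequency of step
frequency with equal amplitudes and zero initial phase:
$SL(s) = SL_0 + a\sin(4\pi s/n)$, $SF(s) = SF_0 + a\sin(2\pi s/n)$. The
amplitude is a configuration parameter with default $a = 0.1$
dimensionless; with that default the centre-region minimum path length
comes out at 21–22 steps. `min_path_length` locates the shortest completed
path by doubling then bisection. Tracking quality is summarized as RMS
errors in percent of the starting gait's step length and frequency.

## What the experiments do and do not show

All experiments here run on the idealized model itself — there is no
measurement noise, no actuator saturation beyond the non-negative
push-off, and full state feedback. Passing tests demonstrate the internal
consistency of the dynamics, the solver, the linearization and the
controllers, and reproduce the model-level quantities (eigenvalue maps,
MTP statistics, response times); they do not validate the model against
human or robot walking data.

Problem sizes used by the test-suite and the acceptance script are chosen
for desk-scale runtimes: a 7×7 fixture grid around the centre gait for
solver verification; every-5th-cell sub-sampling (solved along dense
0.01-frequency rows) for the eigenvalue map; an every-10th-gait lattice
for the MTP means; and the five representative gaits for the response-time
tables. The full 101×101 grid is reproducible with the same functions via
`continuation_sweep(c(0.1, 1.1), c(0.1, 1.1), 0.01)`.

## Known limitations

* The low-frequency fringe (SF ≈ 0.1) can leave a few cells unsolved even
  after retries; they are flagged and excluded from summaries.
* Reported response times at the most gain-sensitive gaits (long step
  length, low step frequency) depend on the deadbeat gain selection among
  the non-unique exact solutions; the package fixes the minimum-norm
  choice.
* The sinusoid amplitude of the path-tracking experiment is a free
  parameter; minimum path lengths scale with it.
* Only the single gait family reached by continuation from the
  long/fast corner is mapped; other families (e.g. multi-oscillation swing
  branches) are deliberately rejected.
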