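---
title: "Direct collocation for muscle-driven multibody models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct collocation for muscle-driven multibody models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and numerical methods the package
implements, the tunable parameters that matter, the design choices made
where the design was genuinely open, and what the verification fixtures do
and do not demonstrate. Everything quantitative stated here is computed by
the package's test suite or by `scripts/acceptance.R`; the vignette states
no result that those do not themselves reproduce.

## The continuous problem

The package solves optimal-control problems over small planar multibody
models: find state trajectories $x(t)$, controls $u(t)$, and optionally a
final time $t_f$ and scalar model parameters $p$ that minimize

$$J = \sum_g w_g \int_{t_0}^{t_f} L_g(x, u, t)\, dt \;+\;
      \sum_g w_g \Phi_g(t_f)$$

subject to the model dynamics, holonomic kinematic constraints
$\varphi(q) = 0$, variable bounds, boundary constraints, and path
constraints. Cost terms cover integrated weighted control powers
(`goal_control_effort`), squared deviation from a reference motion
(`goal_state_tracking`), the duration (`goal_final_time`), and the squared
joint-reaction force (`goal_joint_reaction`).

### Multibody dynamics

Models are trees of planar rigid bodies connected by pin, slider, weld,
planar, or point joints, with minimal coordinates $q$ and speeds
$u = \dot q$. The inverse-dynamics pass is the primitive: body
accelerations are propagated analytically through the tree and projected
onto the coordinates through mass-center Jacobians obtained by complex-step
differentiation of the position kinematics (exact to machine precision for
the sine/cosine/square-root arithmetic involved). The mass matrix is
extracted column-wise from inverse dynamics with unit accelerations, and
forward dynamics solves the constrained equations of motion

$$\begin{bmatrix} M(q) & G(q)^T \\ G(q) & 0 \end{bmatrix}
  \begin{bmatrix} \ddot q \\ -\lambda \end{bmatrix} =
  \begin{bmatrix} \tau - c(q, u) \\ -\dot G u \end{bmatrix},$$

with $G = \partial\varphi/\partial q$. Forward/inverse round-trips are
exact by construction (tested to $10^{-10}$ on random states), and an
unactuated pendulum integrated for 2 s conserves energy to better than
$10^{-6}$ relative (measured: $\sim 10^{-10}$), which validates the
dynamics independently of any optimization.

Applied forces comprise Hill-type muscle path forces mapped through moment
arms $r_j = -\partial \ell_{MT}/\partial q_j$ (complex-step exact),
torsional springs $-k (q - q_0)$, ideal coordinate actuators, smooth
sphere-plane contact, and the constraint coupling $G^T \lambda$.

### Muscle model

Each muscle is a smooth Hill-type unit: a Gaussian active force-length
curve, an exponential passive curve, a logarithmic force-velocity curve, an
exponential tendon curve, first-order activation dynamics with a tanh-
smoothed switch between activation ($\tau_{act} = 15$ ms) and deactivation
($\tau_{deact} = 60$ ms), and normalized fiber damping $\beta = 0.1$. The
curve constants are fixed by this package (documented in
`muscle_params()`); the verification fixtures are built from these same
curves, so their pass/fail status does not hinge on matching any external
coefficient set.

Two tendon modes exist. With a rigid tendon the fiber state follows from
the path length under the constant-thickness pennation model and the
muscle adds only its activation state. With a compliant tendon the
normalized tendon force $\tilde f_T$ becomes a state: its derivative is an
auxiliary control scaled by 50 s$^{-1}$ (so the control variable is
order-one), and fiber-tendon equilibrium is enforced as an algebraic path
residual at every collocation point, with the tendon curve inverted in
closed form. With $\beta > 0$ the residual is strictly monotone in
$\tilde f_T$, so the equilibrium is unique (property-tested by bisection
and a monotonicity sweep).

Two smoothing choices keep the transcribed dynamics $C^1$ over the whole
variable-bound box the solver explores: the raw tendon curve (slightly
negative at slack length, about $-0.012$) is floored through a softplus of
sharpness 100 where it is forward-evaluated, and the rigid-tendon fiber
projection is floored through a softplus of width $0.02\,l_{opt}$ so a
muscle whose path shortens to the tendon slack length during solver
exploration produces a smoothly vanishing force instead of an evaluation
error. Both floors are inactive in the physical interior.

Fiber damping can transmit small compressive forces when a nearly inactive
fiber shortens quickly; this is a documented property of the damped model
and is not suppressed.

### Contact

The sphere-plane contact force is
$F_n = k_c\, d_s^{3/2} (1 + 1.5\, c_d\, v_n)$ with the smoothed depth
$d_s = \tfrac12 (d + \sqrt{d^2 + \epsilon^2})$ and a regularized friction
force $-\mu F_n \tanh(v_t / v_s)$. The smoothing constants default to
$\epsilon = 10^{-4}$ m and $v_s = 0.05$ m/s, chosen so the force is
$C^1$ at gait-like speeds; both are per-element settings. Forces are
applied at the sphere center, adequate for the point-like bodies used at
desk scale.

### Joint reaction loads

The reaction at a joint is the Newton-Euler balance of the subtree distal
to it, $F = \sum_i (m_i a_i - m_i g - f_{ext,i})$, reported as the force
part in the child-body frame. The frame and force-only convention are this
package's documented choice; nothing in the source material fixes them.

## Transcription

Two schemes are provided. Trapezoidal collocation uses $N+1$ mesh points
and the defect $x_{k+1} - x_k - \tfrac h2 (f_k + f_{k+1})$, exact for
state derivatives linear in time. Hermite-Simpson uses $2N+1$ time points
(a collocation point at every interval midpoint) with the Hermite
interpolation defect and the Simpson integration defect, exact through
cubics. Both exactness degrees are asserted symbolically on monomials.

Decision variables are the states and controls at every grid point, an
optional duration (free final time is handled by normalizing time to
$[0,1]$, so $h = \Delta t/N$), Hermite-Simpson midpoint velocity
corrections $\gamma$, and free parameters. Controls are piecewise linear
between grid points, with midpoint values free — with one exception:
constraint-multiplier columns $\lambda$ have their midpoint values tied to
the linear interpolant of the interval endpoints by explicit constraint
rows. Free midpoint multipliers admit a sawtooth null mode under the
Simpson weights (alternating values cancel in the integrated dynamics),
which drifts $\lambda$ to its bounds and distorts the solution; the tie
removes the null mode while leaving the multipliers order-one and
physically interpretable.

Holonomic constraints contribute position- and velocity-level rows
($\varphi = 0$, $G u = 0$) at every mesh point; multipliers enter the
dynamics everywhere; at midpoints only, the coordinate derivative is
augmented with $G^T\gamma$, $|\gamma| \le 0.1$, which lets midpoint states
drift off the constraint manifold by a bounded correction while the mesh
points stay on it. Acceleration-level consistency is implied by the
dynamics defects.

Multibody dynamics can be transcribed explicitly (forward dynamics inside
the state derivative) or implicitly (accelerations $w$ become controls and
the residual `inverse_dynamics(q,u,w) - applied forces = 0` is a path
constraint at every point). Both modes solve the same continuous problem;
the test suite checks that their objectives agree to $10^{-3}$ relative on
the fixtures.

Scaling: defect rows are divided by the characteristic magnitude of their
state (half the bound range), and implicit-dynamics rows by the
characteristic generalized force at the mid-box pose, so all residuals are
order-one. Tolerances refer to these scaled residuals.

## The nonlinear-program solver

No installed sparse NLP solver fits collocation-scale problems, so the
package ships its own: a sparse augmented-Lagrangian method with
projected-Newton inner iterations.

Derivatives use structure-exploiting central finite differences (step
$10^{-6}$, the package default): grid points three apart never share a
constraint row, so a mod-3 coloring of the per-point variable columns
yields the full sparse Jacobian in $O(n_x + n_u)$ evaluations independent
of the mesh size. The objective is carried as a vector of per-point
quadrature contributions with the same banded structure, so its gradient
comes from the same evaluations, as do — from the second differences
against the base point — the exact diagonals of the constraint and
objective Hessians. The inner Newton model is
$\rho J^T J + \mathrm{diag}\big(\nabla^2_{jj} L_A\big)^+ + \delta I$
(Gauss-Newton row-space curvature plus the exact, clamped
augmented-Lagrangian diagonal), factorized with a sparse Cholesky
decomposition; bounds are handled by an active-set projection with a
backtracking line search, and $\delta$ adapts Levenberg-style to the step
quality. During loose phases the Jacobian switches to forward differences
with the curvature diagonals cached from the last central iteration.

Globalization: a feasibility-first phase minimizes $\|c\|^2$ with the
objective off (and a free duration frozen at its guess — shrinking the
horizon spuriously shrinks defect norms without approaching the feasible
manifold) before multiplier estimates exist. Outer iterations apply
first-order multiplier updates; the penalty grows only while the violation
stagnates and is capped at $10^7$ so finite-difference noise is not
amplified through $\rho J^T c$. When dual progress stalls at feasibility,
the penalty restarts at its initial value with the accumulated multipliers
(the multipliers then carry the information the penalty was substituting
for); after convergence a short polish phase sharpens the primal iterate
along near-flat directions where the projected-gradient measure sits at
its finite-difference noise floor. The solver returns its best iterate
even without convergence, flagged `max-iterations` or `infeasible`.

Defaults follow the package's settings table: convergence tolerance
$10^{-3}$ on the KKT conditions, constraint tolerance $10^{-3}$; the
verification fixtures run at $10^{-6}$/$10^{-6}$ so their results are
discretization-limited rather than solver-limited.

The default initial guess is the midpoint of the variable bounds.
Re-solving from a previous solution (guess chaining, with warm-started
multipliers) converges in a handful of iterations, and the predictive
fixtures chain from a coarse mesh to the fine one.

## Tools

`solve_inverse` prescribes the motion exactly: coordinates, speeds, and
accelerations are fixed from cubic interpolants of the supplied
kinematics (when speed columns are present their single derivative is
used for the accelerations — much better conditioned than a second
derivative of the coordinates), and the muscle and reserve-actuator
controls become the unknowns of a small collocation problem whose path
constraint equates produced and required generalized forces. Because the
prescribed kinematics fix the fiber lengths, the muscle force is affine in
activation and the balance rows are linear. Reserve actuators default to
$\pm 2.5$ N m; for the point-mass fixture the tests size them at 0.25 N,
the same few-percent fraction of the task's peak loads that the default
represents for human-scale joint moments. Rigid-tendon muscles only;
cubic-interpolant differentiation has endpoint artifacts, so recovery
comparisons trim 5% of the horizon at each end (the standard
inverse-dynamics edge-effect practice).

`solve_track` penalizes deviation from the reference kinematics together
with control effort, leaving the motion free. `forward_shooting`
integrates the same explicit dynamics code the transcription evaluates,
with an adaptive Dormand-Prince 4/5 pair (relative tolerance $10^{-8}$)
and the same piecewise-linear control interpolation, so
prediction-vs-time-stepping comparisons test the transcription rather
than a reimplementation of the dynamics.

## Verification fixtures and what they show

**Linear tangent steering.** Minimum-time planar thrust steering with
constant acceleration $a = 100$ m/s$^2$ to $y_f = 5$ m, $v_{xf} = 45$
m/s, $v_{yf} = 0$ — the standard instance of this benchmark family. The
optimal control obeys $\tan\theta(t)$ linear in $t$; by the terminal
symmetry the boundary conditions reduce to one scalar root-solve, and the
analytic states follow in closed form (antiderivatives of $\sinh^{-1}$
and $\sqrt{1+p^2}$). The oracle never touches the collocation code. At
Hermite-Simpson $N = 100$ and tolerances $10^{-6}$ the pooled RMS error
over the four states and the control at the grid points is a few
$10^{-6}$, an order below the $2.7\times 10^{-5}$ bound the suite
asserts. Which variables and grid that RMS pools over is this package's
documented choice.

**Suspended point mass.** Three muscles ($F_{iso} = 40$ N,
$l_{opt} = 0.10$ m, $l_{slack} = 0.05$ m, rigid tendons, activation
dynamics) suspend a 1 kg mass from anchors at $x = -0.16, 0, 0.16$ m.
Two fixture-level choices matter and are deliberate:

* *Passive curve disabled.* Over the working box the fibers sit at
  1.3-3.3 times optimal length, where the default passive curve would
  produce forces from tens of newtons to meganewtons — passive force alone
  would dwarf the 9.8 N gravity load and static equilibrium would need no
  activation, inverting the fixture's intent. With `f_pass_scale = 0`
  (the standard ignore-passive-force switch) the fixture probes activation
  dynamics and redundancy, as intended.
* *Static-hold start.* "Starting at rest" pins the initial activations to
  the minimum-norm static-equilibrium values at the start pose. A free
  initial activation is a costless state (effort penalizes excitations),
  which the optimizer can spike arbitrarily; with free initial activations
  the problem had several local optima differing by a few percent, which
  broke mesh-convergence and cross-scheme comparisons. With the static
  hold every solve lands on one optimum and the mesh ladder contracts
  cleanly (normalized objectives 0.996/0.999/1.000 at $N = 10/20/40$).

The prediction (effort weight 1 plus duration weight 0.1, free horizon,
rest-to-rest over 0.16 m) is then checked two ways: a time-stepping
forward simulation driven by the predicted controls reproduces the
position trajectory to a small fraction of the endpoint distance (bound
1.8%), and tracking the predicted motion (tracking weight 10, effort
weight 0.001, same mesh, fixed horizon) recovers the predicted activations
to a small fraction of their peak (bound 0.47%). Both bounds are met with
one to two orders of magnitude of margin. These are consistency checks of
the transcription against independent integration and against its own
optimum — they validate the machinery, not any claim about real muscle.

**Sliding mass.** The bang-bang minimum time $2\sqrt{md/F_{max}}$ is met
to $10^{-4}$ s at Hermite-Simpson $N = 40$. Because free midpoint
controls represent this bang-bang solution essentially exactly once the
switch lands on a mesh point, the third-order scheme's error floors at
solver precision instead of decreasing monotonically; the textbook
monotone mesh-convergence pattern is therefore demonstrated with the
second-order scheme, and the third-order ladder is asserted monotone
until that floor.

**Sit-to-stand with an assistive spring.** A 35 kg inverted pendulum on a
knee-like pin, an extensor and a flexor muscle, effort and duration
weights both 1, starting from a relaxed crouch (initial activations near
the floor, so peak activation reflects the motion). Freeing a knee
torsional-spring stiffness $k \in [0, 300]$ N m/rad can only improve the
objective (zero stiffness remains feasible) and lowers the extensor's
peak activation; the optimum is interior (about 87 N m/rad at these
settings, computed by the suite). Registering the stiffness as a free
parameter and tracking all states of a motion synthesized at
$k^* = 50$ recovers $k^*$ to well within 5%; tracking the kinematics
alone would not identify $k$ (any stiffness can be compensated by
antagonist co-activation), so the recovery experiment tracks activations
too.

**Coupler-constrained chain.** A double pendulum with the elbow slaved to
the shoulder ($q_2 = 2 q_1$) through a holonomic coupler, driven by one
torque actuator, checks the Lagrange-multiplier machinery: position- and
velocity-level residuals at every mesh point stay within the constraint
tolerance, and the multipliers are order-one and penalty-independent.

**What passing does not show.** All fixtures are planar, noise-free,
desk-scale, and solved from either the midpoint guess or a chained coarse
solve. They exercise the transcription, the solver, and the muscle and
multibody dynamics; they say nothing about 3-D systems, measurement
noise, marker data, wrapping muscle paths, or model personalization, all
of which are out of scope.

## Problem sizes and runtimes

The suite solves, among others: the steering benchmark at $N = 100$
(about 1000 variables), the suspended-mass prediction at $N = 50$ (about
1000 variables; roughly half a minute), tracking and inverse recoveries
on the same mesh, the sit-to-stand experiments at $N = 25$, and the
coupler fixture at $N = 20$. The full suite and the acceptance script
each run in minutes on one CPU; these sizes were chosen so the
verification metrics are discretization-limited while iteration remains
comfortable.

## Known limitations

* Planar mechanics only; straight-line muscle paths with via points (no
  wrapping surfaces); no generic model import from external formats.
* Uniform meshes; single phase; no unilateral (complementarity)
  constraints; no mesh refinement.
* The in-house solver is robust on the fixture class it was built for but
  is not a general-purpose interior-point method; hard problems may
  require guess chaining or mesh continuation, which the tools make easy.
* `solve_inverse` supports rigid-tendon muscles only.
* Tracking requires a fixed time horizon, and control-bound envelopes
  require one too.
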