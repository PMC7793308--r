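# ---------------------------------------------------------------------------
# Verification fixtures: runnable benchmark problems with independent
# reference solutions (analytic, forward-simulation, or prior-solution).
# ---------------------------------------------------------------------------

#' Sliding-mass minimum-time problem
#'
#' A 1 kg block on a frictionless slider must travel `distance` metres,
#' starting and ending at rest, with a bounded force `|F| <= f_max`; the
#' duration is minimized. The optimum is the bang-bang law with objective
#' `2 sqrt(m d / F_max)`.
#'
#' @param mass block mass (kg).
#' @param distance travel distance (m).
#' @param f_max force bound (N).
#' @return an [ocp()].
#' @export
sliding_mass_problem <- function(mass = 1, distance = 1, f_max = 10) {
  mod <- mbs_model(gravity = c(0, 0))
  mod <- add_body(mod, "block", mass, joint = "slider", axis = c(1, 0),
                  coords = "x", coord_range = c(-5, 5),
                  speed_range = c(-20, 20))
  mod <- add_coordinate_actuator(mod, "x", name = "force", gain = 1,
                                 control_range = c(-f_max, f_max))
  prob <- ocp(mod, tf = c(0.1, 5))
  prob <- set_state_info(prob, "x", initial = 0, final = distance)
  prob <- set_state_info(prob, "x_u", initial = 0, final = 0)
  add_goal(prob, goal_final_time(1))
}

#' Analytic minimum time of the sliding-mass problem
#' @rdname sliding_mass_problem
#' @export
sliding_mass_min_time <- function(mass = 1, distance = 1, f_max = 10)
  2 * sqrt(mass * distance / f_max)

# ---------------------------------------------------------------------------
# Linear tangent steering
# ---------------------------------------------------------------------------

#' Linear tangent steering benchmark
#'
#' Minimum-time planar thrust-steering problem with constant acceleration
#' magnitude `a`: states `(x, y, v_x, v_y)`, control steering angle `theta`,
#' dynamics `vdot_x = a cos(theta)`, `vdot_y = a sin(theta)`, from the
#' origin at rest to the terminal manifold `y = y_f`, `v_x = v_xf`,
#' `v_y = 0` (`x` free). The optimal control satisfies the linear tangent
#' law `tan(theta(t)) = p0 + pdot t`; by the terminal symmetry the optimal
#' tangent is odd about the midpoint, which reduces the boundary conditions
#' to a single root-solve for `p0` (with the final time following in closed
#' form). [linear_tangent_analytic()] evaluates the closed-form optimal
#' states and control and is fully independent of the collocation code.
#'
#' @param accel thrust acceleration a (m/s^2).
#' @param y_f terminal height (m).
#' @param v_xf terminal horizontal speed (m/s).
#' @return `linear_tangent_steering_problem()`: an [ocp()];
#'   `linear_tangent_analytic()`: list with `tf`, `p0`, `pdot`, and
#'   `traj(t)` returning a matrix of `(x, y, v_x, v_y, theta)`.
#' @export
linear_tangent_steering_problem <- function(accel = 100, y_f = 5,
                                            v_xf = 45) {
  dyn <- function(t, X, U, pars)
    cbind(X[, 3], X[, 4], accel * cos(U[, 1]), accel * sin(U[, 1]))
  states <- data.frame(
    name = c("x", "y", "vx", "vy"),
    lower = c(0, 0, 0, -20), upper = c(50, 20, 60, 20))
  controls <- data.frame(name = "theta", lower = -1.5, upper = 1.5)
  prob <- ocp(model = NULL, tf = c(0.1, 2), dynamics = dyn,
              states = states, controls = controls)
  prob <- set_state_info(prob, "x", initial = 0)
  prob <- set_state_info(prob, "y", initial = 0, final = y_f)
  prob <- set_state_info(prob, "vx", initial = 0, final = v_xf)
  prob <- set_state_info(prob, "vy", initial = 0, final = 0)
  add_goal(prob, goal_final_time(1))
}

#' @rdname linear_tangent_steering_problem
#' @export
linear_tangent_analytic <- function(accel = 100, y_f = 5, v_xf = 45) {
  a <- accel
  s <- function(p) asinh(p); r <- function(p) sqrt(1 + p^2)
  # symmetric optimum: tan(theta) runs from +p0 to -p0, pdot = -2 p0 / tf;
  # v_x(tf) = v_xf fixes tf(p0); y(tf) = y_f provides the scalar root.
  tf_of <- function(p0) v_xf * p0 / (a * s(p0))
  yres <- function(p0) {
    tf <- tf_of(p0)
    a * tf^2 * (p0 * r(p0) - s(p0)) / (4 * p0^2) - y_f
  }
  root <- stats::uniroot(yres, c(1e-6, 50), tol = 1e-14)
  if (abs(yres(root$root)) > 1e-8)
    stop("analytic boundary-condition root-solve did not converge")
  p0 <- root$root
  tf <- tf_of(p0)
  pdot <- -2 * p0 / tf
  traj <- function(t) {
    p <- p0 + pdot * t
    vx <- (a / pdot) * (s(p) - s(p0))
    vy <- (a / pdot) * (r(p) - r(p0))
    Sint <- function(p) p * s(p) - r(p)          # antiderivative of asinh
    Rint <- function(p) (p * r(p) + s(p)) / 2    # antiderivative of sqrt(1+p^2)
    x <- (a / pdot^2) * (Sint(p) - Sint(p0) - s(p0) * (p - p0))
    y <- (a / pdot^2) * (Rint(p) - Rint(p0) - r(p0) * (p - p0))
    cbind(x = x, y = y, vx = vx, vy = vy, theta = atan(p))
  }
  list(tf = tf, p0 = p0, pdot = pdot, traj = traj)
}

# ---------------------------------------------------------------------------
# Suspended point mass: three muscles under gravity
# ---------------------------------------------------------------------------

#' Three-muscle suspended point-mass model
#'
#' A planar 1 kg point mass hangs below the ceiling line `y = 0` from three
#' identical rigid-tendon muscles ("left", "middle", "right") anchored at
#' `(-0.16, 0)`, `(0, 0)`, and `(0.16, 0)` m, with activation dynamics.
#' Muscle parameters: `F_iso = 40` N, `l_opt = 0.10` m, `l_slack = 0.05` m,
#' no pennation. The working box is `x in [-0.12, 0.12]`,
#' `y in [-0.25, -0.05]` m.
#'
#' Over this box the fibers operate at 1.3-3.3 times optimal length, so the
#' passive fiber curve is disabled (`f_pass_scale = 0`): otherwise passive
#' force alone would exceed the gravity load everywhere and static
#' equilibrium would not require activation. The fixture probes activation
#' dynamics and muscle redundancy, not passive-tissue response.
#'
#' @return an [mbs_model()].
#' @export
suspended_mass_fixture <- function() {
  mod <- mbs_model()
  mod <- add_body(mod, "mass", mass = 1, joint = "point",
                  coords = c("x", "y"),
                  coord_range = rbind(c(-0.12, 0.12), c(-0.25, -0.05)),
                  speed_range = c(-5, 5))
  pars <- muscle_params(f_iso = 40, l_opt = 0.10, l_slack = 0.05,
                        alpha_opt = 0, rigid_tendon = TRUE,
                        curves = list(f_pass_scale = 0))
  anchors <- list(left = c(-0.16, 0), middle = c(0, 0), right = c(0.16, 0))
  for (nm in names(anchors))
    mod <- add_muscle(mod, nm, pars,
                      list(list(body = "ground", xy = anchors[[nm]]),
                           list(body = "mass", xy = c(0, 0))))
  mod
}

# Minimum-norm static-hold activations at a pose: least-squares solution of
# the two force-balance equations over the three muscle activations (all
# positive at the fixture's working poses).
suspended_mass_static_activation <- function(mod, q) {
  g <- mod$gravity
  A <- matrix(0, 2, length(mod$muscles))
  for (i in seq_along(mod$muscles)) {
    mus <- mod$muscles[[i]]
    pk <- muscle_path_kinematics(mod, q, c(0, 0), mus)
    fk <- rigid_tendon_kinematics(pk$l_mt, 0, mus$params)
    cv <- muscle_curves(fk$lm_tilde, 0, 1, mus$params)
    # generalized force per unit activation (damping and passive are zero
    # at rest for this fixture)
    A[, i] <- as.numeric(pk$arms) * mus$params$f_iso * fk$cos_alpha *
      cv$f_act * cv$f_v
  }
  b <- -g # balance gravity
  # minimum-norm solution of the underdetermined balance, clamped into the
  # activation bounds
  a0 <- as.numeric(t(A) %*% solve(A %*% t(A), b))
  a0 <- pmin(pmax(a0, 0.01), 1)
  names(a0) <- names(mod$muscles)
  a0
}

#' Predict the suspended point-mass motion
#'
#' Minimum effort-plus-time prediction: move the mass from rest at
#' `(-0.08, -0.18)` m to rest at `(0.08, -0.18)` m, minimizing the
#' integrated sum of squared muscle excitations (weight 1) plus the final
#' time (weight 0.1) over a free horizon.
#'
#' The fine mesh is warm-started from a coarse-mesh solution of the same
#' problem (guess chaining: the solution of one problem is the initial
#' guess for the next); the coarse solve starts from the default
#' midpoint-of-bounds guess.
#'
#' @param n_intervals mesh intervals (default 50).
#' @param scheme transcription scheme.
#' @param dynamics_mode `"explicit"` or `"implicit"`.
#' @param conv_tol,con_tol solver tolerances.
#' @param coarse_n coarse mesh used for the warm-start solve (skipped when
#'   a `guess` is supplied or `coarse_n >= n_intervals`).
#' @param guess,verbose passed to [solve_ocp()].
#' @return an `oc_solution`.
#' @export
predict_suspended_mass <- function(n_intervals = 50,
                                   scheme = "hermite-simpson",
                                   dynamics_mode = "explicit",
                                   conv_tol = 1e-6, con_tol = 1e-6,
                                   coarse_n = 12, guess = NULL,
                                   verbose = FALSE) {
  mod <- suspended_mass_fixture()
  prob <- ocp(mod, tf = c(0.1, 2))
  prob <- set_state_info(prob, "x", initial = -0.08, final = 0.08)
  prob <- set_state_info(prob, "y", initial = -0.18, final = -0.18)
  prob <- set_state_info(prob, "x_u", initial = 0, final = 0)
  prob <- set_state_info(prob, "y_u", initial = 0, final = 0)
  # "starting at rest" means a static hold: initial activations are pinned
  # to the minimum-effort static equilibrium at the start pose. A free
  # initial activation is a costless state the optimizer can spike
  # arbitrarily (excitations, not activations, are penalized), which makes
  # the optimum non-unique.
  a0 <- suspended_mass_static_activation(mod, c(-0.08, -0.18))
  for (i in seq_along(a0))
    prob <- set_state_info(prob, paste0(names(a0)[i], "_activation"),
                           initial = a0[i])
  prob <- add_goal(prob, goal_control_effort(weight = 1))
  prob <- add_goal(prob, goal_final_time(weight = 0.1))
  if (is.null(guess) && coarse_n < n_intervals) {
    cfg0 <- transcription_config(scheme, coarse_n,
                                 dynamics_mode = dynamics_mode,
                                 conv_tol = conv_tol, con_tol = con_tol)
    guess <- solve_ocp(prob, cfg0, verbose = verbose)
  }
  cfg <- transcription_config(scheme, n_intervals,
                              dynamics_mode = dynamics_mode,
                              conv_tol = conv_tol, con_tol = con_tol)
  solve_ocp(prob, cfg, guess = guess, verbose = verbose)
}

#' Prediction vs. time-stepping consistency check
#'
#' Drives a time-stepping forward simulation (adaptive Dormand-Prince,
#' relative tolerance 1e-8) with the predicted controls from the predicted
#' initial state and reports the RMS deviation of the point-mass position
#' as a percentage of the distance between the prescribed initial and final
#' positions.
#'
#' @param prediction a solution from [predict_suspended_mass()] (solved
#'   fresh when omitted).
#' @return list with `rms_m` (RMS position error, m), `pct` (percentage of
#'   the endpoint distance), and the shooting trajectory.
#' @export
prediction_shooting_consistency <- function(prediction = NULL) {
  if (is.null(prediction)) prediction <- predict_suspended_mass()
  mod <- suspended_mass_fixture()
  x0 <- prediction$states[1, ]
  sh <- forward_shooting(mod, prediction, x0,
                         t_span = range(prediction$time),
                         t_out = prediction$time, rtol = 1e-8)
  dx <- sh$states[, "x"] - prediction$states[, "x"]
  dy <- sh$states[, "y"] - prediction$states[, "y"]
  rms <- sqrt(mean(dx^2 + dy^2))
  dist <- 0.16
  list(rms_m = rms, pct = 100 * rms / dist, shooting = sh)
}

#' Tracking-recovery check
#'
#' Tracks the predicted motion (coordinates and speeds, tracking weight 10,
#' squared-excitation weight 0.001, same mesh, horizon fixed to the
#' predicted duration) and reports the RMS error of the three recovered
#' activation trajectories as a percentage of the peak predicted
#' activation.
#'
#' @param prediction a solution from [predict_suspended_mass()] (solved
#'   fresh when omitted).
#' @param tracking_weight,effort_weight goal weights.
#' @param conv_tol,con_tol solver tolerances.
#' @return list with `pct` (RMS as % of peak predicted activation), the
#'   tracking solution, and the per-channel RMS.
#' @export
tracking_recovery <- function(prediction = NULL, tracking_weight = 10,
                              effort_weight = 0.001,
                              conv_tol = 1e-6, con_tol = 1e-6) {
  if (is.null(prediction)) prediction <- predict_suspended_mass()
  mod <- suspended_mass_fixture()
  n_mesh <- (length(prediction$time) - 1) / 2
  cfg <- transcription_config("hermite-simpson", n_mesh,
                              conv_tol = conv_tol, con_tol = con_tol)
  sol <- solve_track(mod, prediction, cfg,
                     tracking_weight = tracking_weight,
                     effort_weight = effort_weight,
                     track_states = c("x", "y", "x_u", "y_u"))
  act_cols <- grep("_activation$", colnames(prediction$states), value = TRUE)
  ref <- prediction$states[, act_cols, drop = FALSE]
  got <- sol$states[, act_cols, drop = FALSE]
  rms <- sqrt(mean((got - ref)^2))
  peak <- max(ref)
  list(pct = 100 * rms / peak, solution = sol,
       rms_per_channel = sqrt(colMeans((got - ref)^2)), peak = peak)
}

# ---------------------------------------------------------------------------
# Mesh-convergence analysis
# ---------------------------------------------------------------------------

#' Mesh-convergence study
#'
#' Solves the same problem over a ladder of mesh densities and reports the
#' objective normalized by the value at the largest number of mesh
#' intervals (which is exactly 1 in its own row).
#'
#' @param problem an [ocp()].
#' @param mesh integer vector of mesh-interval counts (>= 3 values).
#' @param scheme,dynamics_mode,conv_tol,con_tol transcription settings.
#' @param chain_guess reuse each solution as the next initial guess.
#' @return data frame with columns `n_intervals`, `objective`,
#'   `normalized`, `status`.
#' @export
convergence_study <- function(problem, mesh = c(5, 10, 20, 40),
                              scheme = "hermite-simpson",
                              dynamics_mode = "explicit",
                              conv_tol = 1e-6, con_tol = 1e-6,
                              chain_guess = TRUE) {
  if (length(mesh) < 3) stop("need at least 3 mesh densities")
  mesh <- sort(as.integer(mesh))
  obj <- numeric(length(mesh)); status <- character(length(mesh))
  g <- NULL
  for (i in seq_along(mesh)) {
    cfg <- transcription_config(scheme, mesh[i],
                                dynamics_mode = dynamics_mode,
                                conv_tol = conv_tol, con_tol = con_tol)
    s <- solve_ocp(problem, cfg, guess = g)
    obj[i] <- s$objective; status[i] <- s$status
    if (chain_guess) g <- s
  }
  data.frame(n_intervals = mesh, objective = obj,
             normalized = obj / obj[length(obj)], status = status)
}

# ---------------------------------------------------------------------------
# Sit-to-stand pendulum with an assistive torsional spring
# ---------------------------------------------------------------------------

#' Single-joint sit-to-stand fixture
#'
#' A simplified sit-to-stand model: an inverted pendulum ("torso", 35 kg,
#' mass center 0.4 m above a knee-like pin joint) driven by an extensor and
#' a flexor muscle on opposite sides of the joint. The knee angle is 0
#' upright; the motion starts crouched at 1 rad and ends upright, at rest.
#'
#' @param spring_stiffness optional fixed torsional spring stiffness at the
#'   knee (N m/rad), equilibrium at the upright pose.
#' @return an [mbs_model()].
#' @export
sit_to_stand_fixture <- function(spring_stiffness = NULL) {
  mod <- mbs_model()
  mod <- add_body(mod, "torso", mass = 35, inertia = 2.0, joint = "pin",
                  com = c(0, 0.40), coords = "knee",
                  coord_range = c(-0.1, 1.2), speed_range = c(-10, 10))
  ext <- muscle_params(f_iso = 4500, l_opt = 0.20, l_slack = 0.36,
                       rigid_tendon = TRUE)
  flx <- muscle_params(f_iso = 400, l_opt = 0.17, l_slack = 0.10,
                       rigid_tendon = TRUE)
  mod <- add_muscle(mod, "extensor", ext,
                    list(list(body = "ground", xy = c(0.30, 0.0)),
                         list(body = "torso", xy = c(0.0, 0.35))))
  mod <- add_muscle(mod, "flexor", flx,
                    list(list(body = "ground", xy = c(-0.15, -0.05)),
                         list(body = "torso", xy = c(-0.03, 0.25))))
  if (!is.null(spring_stiffness))
    mod <- add_torsional_spring(mod, "knee", spring_stiffness,
                                equilibrium = 0, name = "knee_spring")
  mod
}

sit_to_stand_problem <- function(model, free_spring = FALSE,
                                 spring_bounds = c(0, 300)) {
  prob <- ocp(model, tf = c(0.3, 2))
  prob <- set_state_info(prob, "knee", initial = 1, final = 0)
  prob <- set_state_info(prob, "knee_u", initial = 0, final = 0)
  # the motion starts from a relaxed crouch: initial activations near the
  # floor, so peak activation reflects the demands of the motion itself
  for (nm in grep("_activation$", model_state_layout(model)$names,
                  value = TRUE))
    prob <- set_state_info(prob, nm, initial = c(0.01, 0.05))
  prob <- add_goal(prob, goal_control_effort(weight = 1))
  prob <- add_goal(prob, goal_final_time(weight = 1))
  if (free_spring)
    prob <- add_parameter(prob, "springs/knee_spring/stiffness",
                          spring_bounds[1], spring_bounds[2], name = "k")
  prob
}

#' Spring-assistance experiment
#'
#' Solves the sit-to-stand prediction twice with the same effort-plus-time
#' cost (both weights 1, no motion tracked): unassisted, and with the
#' stiffness of a knee torsional spring registered as a free parameter in
#' `[0, 300]` N m/rad. Since zero stiffness is feasible, the assisted
#' optimal objective can never exceed the unassisted one; a stiffness at a
#' bound triggers a warning (possibly bound-limited optimum).
#'
#' @param n_intervals mesh intervals.
#' @param conv_tol,con_tol solver tolerances.
#' @param spring_bounds stiffness bounds (N m/rad).
#' @return list with `unassisted`, `assisted` (solutions), and `k_opt`.
#' @export
spring_assist_experiment <- function(n_intervals = 25, conv_tol = 1e-6,
                                     con_tol = 1e-6,
                                     spring_bounds = c(0, 300)) {
  cfg <- transcription_config("hermite-simpson", n_intervals,
                              conv_tol = conv_tol, con_tol = con_tol)
  un <- solve_ocp(sit_to_stand_problem(sit_to_stand_fixture()), cfg)
  mod_s <- sit_to_stand_fixture(spring_stiffness = 0)
  prob_s <- sit_to_stand_problem(mod_s, free_spring = TRUE,
                                 spring_bounds = spring_bounds)
  as_ <- solve_ocp(prob_s, cfg, guess = un)
  k <- as.numeric(as_$parameters["k"])
  if (k <= spring_bounds[1] + 1e-6 || k >= spring_bounds[2] - 1e-6)
    warning("optimal stiffness k = ", format(k),
            " sits at a bound; the optimum may be bound-limited")
  list(unassisted = un, assisted = as_, k_opt = k)
}

# ---------------------------------------------------------------------------
# Coupler-constrained two-link fixture
# ---------------------------------------------------------------------------

#' Two-link chain with a coordinate-coupler constraint
#'
#' A planar double pendulum whose elbow angle is coupled to the shoulder
#' angle (`q2 = ratio * q1`), driven by a single torque actuator on `q1`.
#' Used to exercise holonomic-constraint handling (multipliers, velocity
#' corrections, position/velocity-level residuals).
#'
#' @param ratio coupler ratio.
#' @return an [mbs_model()].
#' @export
coupler_fixture <- function(ratio = 2) {
  mod <- mbs_model()
  mod <- add_body(mod, "link1", mass = 1.5, inertia = 0.02, joint = "pin",
                  com = c(0, -0.25), coords = "q1",
                  coord_range = c(-2, 2), speed_range = c(-15, 15))
  mod <- add_body(mod, "link2", mass = 1.0, inertia = 0.01, parent = "link1",
                  joint = "pin", joint_parent = c(0, -0.5),
                  com = c(0, -0.2), coords = "q2",
                  coord_range = c(-3, 3), speed_range = c(-15, 15))
  mod <- add_coordinate_actuator(mod, "q1", name = "tau1", gain = 10,
                                 control_range = c(-5, 5))
  mod <- add_constraint(mod, "coordinate_coupling", coords = c("q1", "q2"),
                        coeffs = c(-ratio, 1), name = "coupler")
  mod
}

coupler_swing_problem <- function(ratio = 2, q1_final = 0.6, tf = 1) {
  mod <- coupler_fixture(ratio)
  prob <- ocp(mod, tf = tf)
  prob <- set_state_info(prob, "q1", initial = 0, final = q1_final)
  prob <- set_state_info(prob, "q2", initial = 0, final = ratio * q1_final)
  prob <- set_state_info(prob, "q1_u", initial = 0, final = 0)
  prob <- set_state_info(prob, "q2_u", initial = 0, final = 0)
  add_goal(prob, goal_control_effort(weight = 1))
}

# ---------------------------------------------------------------------------
# Verification driver
# ---------------------------------------------------------------------------

#' Run the verification suite
#'
#' Executes the analytic steering benchmark, the prediction/time-stepping
#' consistency check, and the tracking-recovery check, and reports each
#' metric against its tolerance. The reference provenance is `analytic` for
#' the steering benchmark, `forward-simulation` for the consistency check,
#' and `prior-solution` for tracking recovery.
#'
#' @param steering_n mesh intervals for the steering benchmark.
#' @param predict_n mesh intervals for the suspended-mass prediction.
#' @param quick use a coarser prediction mesh (for interactive smoke runs).
#' @param prediction optional precomputed [predict_suspended_mass()]
#'   solution, reused for the consistency and tracking fixtures.
#' @return data frame of class `fixture_report` with columns `fixture`,
#'   `metric`, `value`, `tolerance`, `pass`, `reference`.
#' @export
run_verification <- function(steering_n = 100, predict_n = 50,
                             quick = FALSE, prediction = NULL) {
  if (quick) { steering_n <- 25; predict_n <- 20 }
  rows <- list()
  st <- steering_accuracy(n_intervals = steering_n)
  rows[[1]] <- data.frame(fixture = "linear_tangent_steering",
                          metric = "rms_states_control", value = st$rms,
                          tolerance = 2.7e-5, pass = st$rms <= 2.7e-5,
                          reference = "analytic")
  pred <- if (!is.null(prediction)) prediction else
    predict_suspended_mass(n_intervals = predict_n)
  cons <- prediction_shooting_consistency(pred)
  rows[[2]] <- data.frame(fixture = "suspended_mass_prediction",
                          metric = "rms_position_pct_of_distance",
                          value = cons$pct, tolerance = 1.8,
                          pass = cons$pct <= 1.8,
                          reference = "forward-simulation")
  tr <- tracking_recovery(pred)
  rows[[3]] <- data.frame(fixture = "tracking_recovery",
                          metric = "rms_activation_pct_of_peak",
                          value = tr$pct, tolerance = 0.47,
                          pass = tr$pct <= 0.47,
                          reference = "prior-solution")
  out <- do.call(rbind, rows)
  class(out) <- c("fixture_report", "data.frame")
  out
}

#' Steering-benchmark accuracy
#'
#' Solves the linear tangent steering problem by collocation and reports
#' the RMS error against the analytic solution, pooled over all four states
#' and the control at the collocation grid points.
#'
#' @param n_intervals mesh intervals.
#' @param conv_tol,con_tol solver tolerances.
#' @return list with `rms`, `tf_err`, the solution, and the analytic
#'   reference.
#' @export
steering_accuracy <- function(n_intervals = 100, conv_tol = 1e-6,
                              con_tol = 1e-6) {
  prob <- linear_tangent_steering_problem()
  cfg <- transcription_config("hermite-simpson", n_intervals,
                              conv_tol = conv_tol, con_tol = con_tol)
  sol <- solve_ocp(prob, cfg)
  ref <- linear_tangent_analytic()
  A <- ref$traj(sol$time)
  got <- cbind(sol$states, sol$controls[, "theta"])
  err <- got - A
  list(rms = sqrt(mean(err^2)), tf_err = max(sol$time) - ref$tf,
       solution = sol, analytic = ref)
}
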