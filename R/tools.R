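# ---------------------------------------------------------------------------
# Tools for standard problems: time-stepping forward simulation, the
# muscle-redundancy (inverse) problem, and motion tracking.
# ---------------------------------------------------------------------------

#' Time-stepping forward simulation
#'
#' Integrates the same continuous dynamics used by the transcription layer
#' (explicit mode) with an adaptive high-order explicit Runge-Kutta
#' integrator (Dormand-Prince 4/5). Controls are interpolated with the same
#' piecewise-linear rule the transcription uses between grid points.
#'
#' @param model an [mbs_model()].
#' @param controls an `oc_trajectory` whose control columns drive the model,
#'   or a function `f(t)` returning the model control vector.
#' @param x0 initial full state (model state ordering).
#' @param t_span `c(t_start, t_end)`.
#' @param t_out output time grid (defaults to 200 uniform samples).
#' @param rtol,atol integration tolerances.
#' @return an `oc_trajectory` with the integrated states.
#' @export
forward_shooting <- function(model, controls, x0, t_span,
                             t_out = NULL, rtol = 1e-8, atol = 1e-10) {
  cl <- model_control_layout(model)
  nu <- cl$ne + cl$nact
  ctrl_fn <- if (is.function(controls)) controls else {
    cols <- lapply(cl$names, function(nm) {
      src <- if (nm %in% colnames(controls$controls)) controls$controls[, nm]
      else if (nm %in% colnames(controls$states)) controls$states[, nm]
      else stop("control column '", nm, "' not found in trajectory")
      stats::approxfun(controls$time, src, rule = 2)
    })
    function(t) vapply(cols, function(f) f(t), 0)
  }
  cfg <- transcription_config()
  dyn_cache <- model_eval_cache(model)
  sl <- model_state_layout(model)
  ns <- 2 * sl$nq + sl$na + sl$nft
  stopifnot(length(x0) == ns)
  m <- n_constraint_eq(model)
  rhs <- function(t, y, p) {
    uc <- matrix(ctrl_fn(t), 1, nu)
    Uall <- cbind(uc, matrix(0, 1, m)) # multiplier-free: lambda solved below
    if (m == 0) {
      d <- mbs_dynamics_batch(model, matrix(y, 1), Uall, cfg,
                              mode = "explicit", cache = dyn_cache)
      return(list(as.numeric(d$Xdot)))
    }
    # constrained models: solve the KKT system for the accelerations
    nq <- sl$nq
    q <- y[seq_len(nq)]; u <- y[nq + seq_len(nq)]
    tau <- applied_generalized_forces(model, matrix(y, 1), uc)
    fd <- forward_dynamics(model, q, u, as.numeric(tau), baumgarte = 20)
    adot <- if (sl$na) vapply(seq_len(sl$na), function(i)
      activation_derivative(uc[1, i], y[2 * nq + i],
                            model$muscles[[i]]$params), 0) else NULL
    list(c(u, fd$qdd, adot))
  }
  if (is.null(t_out)) t_out <- seq(t_span[1], t_span[2], length.out = 200)
  out <- deSolve::ode(y = as.numeric(x0), times = t_out, func = rhs,
                      parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("forward integration failed")
  st <- unname(out[, -1, drop = FALSE])
  st <- matrix(st, nrow = length(t_out))
  colnames(st) <- sl$names
  uc <- t(vapply(t_out, ctrl_fn, numeric(nu)))
  uc <- matrix(uc, nrow = length(t_out))
  colnames(uc) <- cl$names
  trajectory(out[, 1], states = st, controls = uc)
}

#' Solve the muscle-redundancy (inverse) problem
#'
#' Prescribes the motion exactly: coordinates, speeds, and accelerations are
#' fixed from twice-differentiated cubic interpolants of the supplied
#' kinematics, and the muscle (and reserve-actuator) controls that reproduce
#' the required generalized forces are solved for. At every collocation
#' point the equality path constraint
#' `muscle forces + reserves = inverse dynamics` is enforced; activation
#' dynamics link excitations and activations along the grid. The objective
#' is the integrated sum of squared controls.
#'
#' Reserve actuators default to a bound of +-2.5 N m, a guideline magnitude
#' small relative to physiological joint moments; pass
#' `reserve_bound = Inf` for a torque-driven solve.
#'
#' @param model an [mbs_model()] (rigid-tendon muscles).
#' @param kinematics an `oc_trajectory` providing every coordinate over the
#'   horizon.
#' @param config a [transcription_config()].
#' @param t_span sub-horizon to solve (defaults to the kinematics span).
#' @param reserve_bound reserve-actuator bound (N m).
#' @param reserve_weight effort weight on reserve controls.
#' @param initial_activation optional vector pinning the initial muscle
#'   activations (one value per muscle). Useful when a muscle produces
#'   negligible force at the starting pose, where its free initial
#'   activation is dynamically unidentifiable.
#' @param guess,verbose passed to [solve_ocp()].
#' @return an `oc_solution`; states are muscle activations, controls are
#'   excitations and reserve controls.
#' @export
solve_inverse <- function(model, kinematics,
                          config = transcription_config(),
                          t_span = NULL, reserve_bound = 2.5,
                          reserve_weight = 1, initial_activation = NULL,
                          guess = NULL, verbose = FALSE) {
  sl <- model_state_layout(model)
  if (sl$nft)
    stop("solve_inverse supports rigid-tendon muscles only")
  cd <- model_coords(model)
  nq <- sl$nq
  missing_q <- setdiff(cd$name, colnames(kinematics$states))
  if (length(missing_q))
    stop("kinematics is missing coordinate column(s): ",
         paste(missing_q, collapse = ", "))
  span <- range(kinematics$time)
  if (is.null(t_span)) t_span <- span
  if (t_span[1] < span[1] - 1e-12 || t_span[2] > span[2] + 1e-12)
    stop("requested horizon lies outside the kinematics data span")
  qfun <- lapply(cd$name, function(nm)
    stats::splinefun(kinematics$time, kinematics$states[, nm],
                     method = "fmm"))
  # fine grid times are fixed (fixed horizon), so everything that depends on
  # the prescribed motion is precomputed at the grid once
  Tt <- build_grid(config, t_span[1], t_span[2])
  n <- length(Tt)
  Q <- vapply(qfun, function(f) f(Tt), numeric(n))
  u_cols <- paste0(cd$name, "_u")
  if (all(u_cols %in% colnames(kinematics$states))) {
    # speed columns present: differentiating them once for the
    # accelerations is far better conditioned than a second derivative of
    # the coordinate interpolant
    ufun <- lapply(u_cols, function(nm)
      stats::splinefun(kinematics$time, kinematics$states[, nm],
                       method = "fmm"))
    U <- vapply(ufun, function(f) f(Tt), numeric(n))
    Qdd <- vapply(ufun, function(f) f(Tt, deriv = 1), numeric(n))
  } else {
    U <- vapply(qfun, function(f) f(Tt, deriv = 1), numeric(n))
    Qdd <- vapply(qfun, function(f) f(Tt, deriv = 2), numeric(n))
  }
  Q <- matrix(Q, n); U <- matrix(U, n); Qdd <- matrix(Qdd, n)
  tau_req <- inverse_dynamics(model, Q, U, Qdd)
  # passive/spring/contact contributions at the prescribed state do not
  # depend on the unknowns; fold them into the required torque
  nmus <- length(model$muscles)
  g1 <- g0 <- arms <- list()
  for (i in seq_len(nmus)) {
    mus <- model$muscles[[i]]
    pk <- muscle_path_kinematics(model, Q, U, mus)
    fk <- rigid_tendon_kinematics(pk$l_mt, pk$v_mt, mus$params)
    cv <- muscle_curves(fk$lm_tilde, fk$vm_tilde, 1, mus$params)
    g1[[i]] <- mus$params$f_iso * fk$cos_alpha * cv$f_act * cv$f_v
    g0[[i]] <- mus$params$f_iso * fk$cos_alpha *
      (cv$f_pass + mus$params$beta * fk$vm_tilde)
    arms[[i]] <- pk$arms
  }
  for (s in model$springs) {
    j <- match(s$coord, cd$name)
    tau_req[, j] <- tau_req[, j] + s$stiffness * (Q[, j] - s$equilibrium)
  }
  mus_names <- if (nmus) names(model$muscles) else character(0)
  exc_names <- if (nmus) paste0(mus_names, "_excitation") else character(0)
  res_names <- paste0(cd$name, "_reserve")
  states <- data.frame(name = paste0(mus_names, "_activation"),
                       lower = 0.01, upper = 1)
  if (!nmus) states <- states[0, ]
  controls <- data.frame(
    name = c(exc_names, res_names),
    lower = c(rep(0.01, nmus), rep(-reserve_bound, nq)),
    upper = c(rep(1, nmus), rep(reserve_bound, nq)))
  act_params <- lapply(model$muscles, `[[`, "params")
  dyn <- function(t, X, Uc, pars) {
    if (!nmus) return(X[, 0, drop = FALSE])
    ad <- matrix(0, nrow(X), nmus)
    for (i in seq_len(nmus))
      ad[, i] <- activation_derivative(Uc[, i], X[, i], act_params[[i]])
    ad
  }
  prob <- ocp(model = NULL, t0 = t_span[1], tf = t_span[2], dynamics = dyn,
              states = states, controls = controls)
  if (!is.null(initial_activation))
    for (i in seq_len(nmus))
      prob <- set_state_info(prob, paste0(mus_names[i], "_activation"),
                             initial = initial_activation[i])
  w <- as.list(c(rep(1, nmus), rep(reserve_weight, nq)))
  names(w) <- c(exc_names, res_names)
  prob <- add_goal(prob, goal_control_effort(weight = 1, weights = w))
  balance <- function(t, X, Uc) {
    stopifnot(length(t) == n) # fixed grid by construction
    r <- -tau_req
    for (i in seq_len(nmus)) {
      f <- g1[[i]] * X[, i] + g0[[i]]
      r <- r + arms[[i]] * f
    }
    r + Uc[, nmus + seq_len(nq), drop = FALSE]
  }
  prob <- add_path_constraint(prob, "custom", fn = balance, n_eq = nq)
  sol <- solve_ocp(prob, config, guess = guess, verbose = verbose)
  sol$prescribed <- trajectory(Tt, states = {
    m <- cbind(Q, U, Qdd)
    colnames(m) <- c(cd$name, paste0(cd$name, "_u"),
                     paste0(cd$name, "_udot"))
    m
  })
  sol
}

#' Solve a motion-tracking problem
#'
#' Solves for both a motion and the muscle (or other actuator) controls: the
#' model dynamics are free, and deviation from the reference kinematics is
#' penalized together with control effort. Unlike [solve_inverse()], the
#' resulting motion may deviate from the reference.
#'
#' @param model an [mbs_model()].
#' @param reference an `oc_trajectory`; every state column matching a model
#'   state is tracked (coordinates and speeds by default).
#' @param config a [transcription_config()].
#' @param tracking_weight,effort_weight goal weights.
#' @param track_states state names to track (default: reference columns that
#'   are model coordinates or speeds).
#' @param guess,lam0,verbose passed to [solve_ocp()].
#' @return an `oc_solution`.
#' @export
solve_track <- function(model, reference, config = transcription_config(),
                        tracking_weight = 1, effort_weight = 0.001,
                        track_states = NULL, guess = NULL, lam0 = NULL,
                        verbose = FALSE) {
  sl <- model_state_layout(model)
  span <- range(reference$time)
  prob <- ocp(model, t0 = span[1], tf = span[2])
  if (is.null(track_states))
    track_states <- intersect(colnames(reference$states),
                              c(sl$q, sl$u))
  if (!length(track_states))
    stop("reference shares no trackable state columns with the model")
  w <- as.list(rep(1, length(track_states)))
  names(w) <- track_states
  prob <- add_goal(prob, goal_state_tracking(reference,
                                             weight = tracking_weight,
                                             weights = w))
  prob <- add_goal(prob, goal_control_effort(weight = effort_weight))
  solve_ocp(prob, config, guess = guess, lam0 = lam0, verbose = verbose)
}
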